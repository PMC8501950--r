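#' Condition presets for the synthetic population
#'
#' Reads the single configuration file that states every per-phase base
#' channel mean and every genotoxin preset (multiplicative and additive
#' per-phase modifiers). `untreated` and `dart_e160a` are identity presets.
#'
#' @param path optional path to an alternative presets JSON; defaults to the
#'   file shipped with the package.
#' @return list with elements `base_means` and `presets`.
#' @export
condition_presets <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "condition_presets.json", package = "qibcr",
                        mustWork = TRUE)
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  stopifnot(is.list(cfg$base_means), is.list(cfg$presets))
  cfg[c("base_means", "presets")]
}

#' True per-channel mean for one phase under a condition preset
#'
#' @param channel channel name (e.g. "EdU").
#' @param phase one of "G1", "S", "G2".
#' @param condition preset name.
#' @param presets output of [condition_presets()].
#' @return single non-negative intensity (A.U., above background).
#' @keywords internal
preset_channel_mean <- function(channel, phase, condition, presets) {
  base <- presets$base_means[[channel]]
  if (is.null(base)) stop("unknown channel: ", channel, call. = FALSE)
  mu <- as.numeric(base[[phase]])
  eff <- presets$presets[[condition]]
  if (is.null(eff))
    stop("unknown condition preset: ", condition, call. = FALSE)
  mod <- eff[[channel]][[phase]]
  if (!is.null(mod)) {
    if (!is.null(mod$mult)) mu <- mu * as.numeric(mod$mult)
    if (!is.null(mod$add)) mu <- mu + as.numeric(mod$add)
  }
  if (mu < 0) stop("preset produced a negative mean", call. = FALSE)
  mu
}
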