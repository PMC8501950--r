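#' Score segmentation recovery against ground truth
#'
#' For every ground-truth nucleus, the detected label with the largest
#' pixel overlap is matched and the intersection-over-union (IoU) of the
#' two pixel sets computed.
#'
#' @param scene a [make_scene()] result.
#' @param mask a `label_mask` from [segment_nuclei()].
#' @return data.frame: one row per ground-truth nucleus with `id`, `phase`,
#'   `partner`, `matched_label` (0 if none) and `iou`.
#' @export
segmentation_recovery <- function(scene, mask) {
  stopifnot(inherits(scene, "synthetic_scene"), inherits(mask, "label_mask"))
  truth <- truth_label_mask(scene)$labels
  det <- mask$labels
  stopifnot(identical(dim(truth), dim(det)))
  n <- nrow(scene$nuclei)
  out <- data.frame(id = scene$nuclei$id, phase = scene$nuclei$phase,
                    partner = scene$nuclei$partner,
                    matched_label = integer(n), iou = numeric(n))
  if (n == 0) return(out)
  det_area <- if (mask$n_objects > 0)
    tabulate(det[det > 0], nbins = mask$n_objects) else integer(0)
  for (k in seq_len(n)) {
    id <- scene$nuclei$id[k]
    tpix <- truth == id
    t_area <- sum(tpix)
    labs <- det[tpix]
    labs <- labs[labs > 0]
    if (length(labs) == 0) next
    tab <- tabulate(labs, nbins = mask$n_objects)
    best <- which.max(tab)
    inter <- tab[best]
    union <- t_area + det_area[best] - inter
    out$matched_label[k] <- best
    out$iou[k] <- inter / union
  }
  out
}

#' Check that planted fused pairs resolve into exactly two labels
#'
#' For each planted touching pair, requires that the two partners match
#' two distinct detected labels and that no third label claims a
#' substantial share (>= 5 percent) of the pair's pixels.
#'
#' @param scene a [make_scene()] result with touching pairs.
#' @param mask a `label_mask`.
#' @return data.frame: one row per pair with `id_a`, `id_b`, `resolved`.
#' @export
fused_pairs_resolved <- function(scene, mask) {
  rec <- segmentation_recovery(scene, mask)
  nuc <- scene$nuclei
  firsts <- which(!is.na(nuc$partner) & nuc$id < nuc$partner)
  truth <- truth_label_mask(scene)$labels
  det <- mask$labels
  res <- lapply(firsts, function(k) {
    a <- nuc$id[k]; b <- nuc$partner[k]
    la <- rec$matched_label[rec$id == a]
    lb <- rec$matched_label[rec$id == b]
    pair_pix <- truth == a | truth == b
    labs <- det[pair_pix]
    labs <- labs[labs > 0]
    share <- if (length(labs) > 0) table(labs) / sum(pair_pix) else numeric(0)
    major <- as.integer(names(share)[share >= 0.05])
    data.frame(id_a = a, id_b = b,
               resolved = la > 0 && lb > 0 && la != lb &&
                 length(major) == 2 && setequal(major, c(la, lb)))
  })
  do.call(rbind, res)
}
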