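#' Per-snapshot relative L2 error
#'
#' `eps_k = ||x_k_truth - x_k_recon|| / ||x_k_truth|| * 100` per frame, in
#' percent.  Frames whose truth norm falls below `low_energy_threshold`
#' times the deck's maximum frame norm are excluded (set to `NA`) rather
#' than allowed to blow the ratio up; the number excluded is attached as
#' attribute `"n_excluded"`.  This is the same criterion that motivates
#' discarding trailing near-zero frames before fitting.
#'
#' @param truth,recon [snapshot_set()]s of identical shape and frame grid.
#' @param low_energy_threshold relative norm cutoff; default `1e-3`.
#' @return Numeric vector of length `Nt` (percent), `NA` at excluded
#'   frames, with attribute `n_excluded`.
#' @export
snapshot_errors <- function(truth, recon, low_energy_threshold = 1e-3) {
  stopifnot(inherits(truth, "snapshot_set"), inherits(recon, "snapshot_set"))
  if (!identical(dim(truth$values), dim(recon$values)))
    stop("decks differ in shape")
  ft <- flatten(truth); fr <- flatten(recon)
  tn <- sqrt(colSums(ft^2))
  dn <- sqrt(colSums((ft - fr)^2))
  excl <- tn < low_energy_threshold * max(tn)
  eps <- ifelse(excl, NA_real_, dn / tn * 100)
  attr(eps, "n_excluded") <- sum(excl)
  eps
}

#' Mean relative error over frames
#'
#' @param eps per-frame error series (percent); `NA` entries (excluded
#'   frames) are dropped.
#' @return Scalar MRE (percent).
#' @export
mean_relative_error <- function(eps) {
  eps <- eps[!is.na(eps)]
  if (length(eps) == 0L) stop("empty error series")
  mean(eps)
}

#' Maximum relative error over frames
#'
#' @param eps per-frame error series (percent).
#' @return Scalar maximum (percent).
#' @export
max_relative_error <- function(eps) {
  eps <- eps[!is.na(eps)]
  if (length(eps) == 0L) stop("empty error series")
  max(eps)
}

#' Full-field and region-restricted error table
#'
#' Assembles per-frame relative errors, their mean (MRE) and maximum, for
#' the full field and for each named region mask (both decks restricted to
#' the masked entities before taking norms).  Two "maximum" statistics are
#' reported per row: `max_eps` (largest per-frame error) and
#' `max_cellwise` (largest per-entity-per-frame relative error
#' `||diff_i,k|| / ||truth_i,k||` over entities with non-negligible truth
#' magnitude), which bounds the worst single-cell deviation.
#'
#' @param truth,recon [snapshot_set()]s; `truth` must carry the masks.
#' @param masks character vector of mask names; default all masks on the
#'   deck.
#' @param low_energy_threshold passed to [snapshot_errors()].
#' @return An object of class `error_report`: a list with `eps`
#'   (full-field series), `table` (data frame: region, MRE, max_eps,
#'   max_cellwise, n_excluded) and metadata.
#' @export
region_error_table <- function(truth, recon, masks = NULL,
                               low_energy_threshold = 1e-3) {
  stopifnot(inherits(truth, "snapshot_set"))
  if (is.null(masks)) masks <- names(truth$masks)
  rows <- list()
  one_region <- function(tr, rc, label) {
    eps <- snapshot_errors(tr, rc, low_energy_threshold)
    data.frame(region = label,
               MRE = mean_relative_error(eps),
               max_eps = max_relative_error(eps),
               max_cellwise = max_cellwise_error(tr, rc,
                                                 low_energy_threshold),
               n_excluded = attr(eps, "n_excluded"),
               stringsAsFactors = FALSE)
  }
  eps_full <- snapshot_errors(truth, recon, low_energy_threshold)
  rows[["full"]] <- one_region(truth, recon, "full_field")
  for (nm in masks) {
    if (is.null(truth$masks) || !nm %in% names(truth$masks))
      stop("mask '", nm, "' missing from truth deck")
    tr <- region_view(truth, nm)
    rc <- region_view_like(recon, truth, nm)
    rows[[nm]] <- one_region(tr, rc, nm)
  }
  structure(list(eps = eps_full,
                 table = do.call(rbind, c(rows, make.row.names = FALSE)),
                 n_frames = n_frames(truth),
                 flow_rate = truth$flow_rate),
            class = "error_report")
}

# restrict `set` with the masks carried by `ref` (reconstructed decks may
# lack masks of their own)
region_view_like <- function(set, ref, mask_name) {
  if (!is.null(set$masks) && mask_name %in% names(set$masks))
    return(region_view(set, mask_name))
  keep <- ref$masks[[mask_name]]
  snapshot_set(set$values[, keep, , drop = FALSE], dt = set$dt,
               kind = set$kind, times = set$times,
               flow_rate = set$flow_rate)
}

# worst per-entity-per-frame relative error, percent; entities/frames with
# truth magnitude below threshold * global max are skipped
max_cellwise_error <- function(truth, recon, low_energy_threshold = 1e-3) {
  tv <- truth$values; rv <- recon$values
  tmag <- sqrt(colSums(tv^2))          # N x Nt entity magnitudes
  dmag <- sqrt(colSums((tv - rv)^2))
  ok <- tmag > low_energy_threshold * max(tmag)
  if (!any(ok)) return(NA_real_)
  max(dmag[ok] / tmag[ok]) * 100
}

#' @export
print.error_report <- function(x, ...) {
  cat(sprintf("<error_report> %d frames%s\n", x$n_frames,
              if (is.null(x$flow_rate)) "" else
                sprintf(", flow = %g L/min", x$flow_rate)))
  print(x$table, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
as.data.frame.error_report <- function(x, ...) x$table
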