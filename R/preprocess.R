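# LOD-based protein filtering, bridging-sample batch harmonization across
# measurement rounds, and assay precision (CV) metrics.

#' Filter proteins by limit-of-detection exceedance
#'
#' A protein is excluded when its values fall below its LOD in more than
#' \code{max_below_frac} of the analysis samples (strictly "more than":
#' exactly 15 percent below LOD is retained at the default). QC and
#' bridging measurements are excluded from the denominator, so adding
#' them never changes a retention decision. Below-LOD values of retained
#' proteins are kept as reported; assays are filtered, values are never
#' masked or imputed.
#'
#' @param npx an \code{\link{npx_matrix}}.
#' @param meta optional metadata; when given, rows with \code{is_qc} or
#'   \code{is_bridging} are dropped from the denominator.
#' @param max_below_frac exclusion threshold on the below-LOD fraction.
#' @return list with \code{npx} (retained proteins only) and \code{qc}
#'   (data.frame: protein_id, below_lod_frac, detectability percent,
#'   retained flag).
#' @export
filter_by_lod <- function(npx, meta = NULL, max_below_frac = 0.15) {
  stopifnot(inherits(npx, "npx_matrix"))
  v <- npx$values
  if (!is.null(meta)) {
    validate_metadata(meta, npx)
    keep <- !(isTRUE_vec(meta$is_qc %||% FALSE) |
                isTRUE_vec(meta$is_bridging %||% FALSE))
    v <- v[meta$sample_id[keep], , drop = FALSE]
  }
  below <- sweep(v, 2, npx$lod, `<`)
  frac <- colMeans(below, na.rm = TRUE)
  frac[is.nan(frac)] <- 0
  retained <- frac <= max_below_frac
  qc <- data.frame(protein_id = protein_ids(npx),
                   below_lod_frac = as.numeric(frac),
                   detectability = 100 * (1 - as.numeric(frac)),
                   retained = as.logical(retained),
                   stringsAsFactors = FALSE)
  list(npx = npx[, retained], qc = qc)
}

#' Remove between-round batch offsets using bridging samples
#'
#' Bridging samples are aliquots measured in every round. For each
#' non-reference round and each protein, the median of (round value minus
#' reference value) over bridging subjects shared with the reference
#' round is subtracted from every measurement of that round; the
#' reference round is unchanged. The median (rather than the mean) keeps
#' the estimate robust with only 16 bridging samples. A per-protein
#' additive shift leaves within-round sample rank order untouched.
#'
#' @param npx an \code{\link{npx_matrix}}.
#' @param meta metadata with \code{round}, \code{is_bridging} and
#'   \code{subject_id} (falls back to \code{sample_id} when absent).
#' @param reference_round round identifier to normalize towards.
#' @return list with \code{npx} (corrected) and \code{offsets}
#'   (data.frame: round, protein_id, offset).
#' @export
bridge_normalize <- function(npx, meta, reference_round = 1) {
  stopifnot(inherits(npx, "npx_matrix"))
  validate_metadata(meta, npx)
  if (!"round" %in% names(meta)) stop("metadata lacks 'round'", call. = FALSE)
  subj <- meta$subject_id %||% meta$sample_id
  is_br <- isTRUE_vec(meta$is_bridging %||% FALSE)
  rounds <- unique(meta$round)
  if (!reference_round %in% rounds)
    stop("reference round '", reference_round, "' not present", call. = FALSE)
  v <- npx$values[meta$sample_id, , drop = FALSE]
  ref_rows <- which(meta$round == reference_round & is_br)
  offsets <- NULL
  for (r in setdiff(rounds, reference_round)) {
    r_rows <- which(meta$round == r & is_br)
    shared <- intersect(subj[r_rows], subj[ref_rows])
    if (length(shared) < 2)
      stop("round '", r, "' shares fewer than 2 bridging samples with the reference",
           call. = FALSE)
    a <- v[meta$sample_id[r_rows][match(shared, subj[r_rows])], , drop = FALSE]
    b <- v[meta$sample_id[ref_rows][match(shared, subj[ref_rows])], , drop = FALSE]
    off <- apply(a - b, 2, stats::median, na.rm = TRUE)
    rows_r <- meta$round == r
    v[rows_r, ] <- sweep(v[rows_r, , drop = FALSE], 2, off, `-`)
    offsets <- rbind(offsets, data.frame(round = r, protein_id = protein_ids(npx),
                                         offset = as.numeric(off),
                                         stringsAsFactors = FALSE))
  }
  out <- npx
  out$values[meta$sample_id, ] <- v
  list(npx = out, offsets = offsets %||%
         data.frame(round = character(0), protein_id = character(0),
                    offset = numeric(0)))
}

#' Intra- and inter-assay precision from QC replicates
#'
#' Coefficients of variation are computed on the linear scale
#' (\code{2^NPX}), because NPX is log2 and a CV of log-scale values is
#' not a coefficient of variation. Intra-assay CV is the mean of
#' within-plate CVs (each \code{100 * sd / mean} over the replicates of
#' one plate); inter-assay CV is the CV of the plate means.
#'
#' @param replicates data.frame with columns \code{qc_sample},
#'   \code{plate}, \code{protein_id}, \code{npx} (log2 scale).
#' @return data.frame: qc_sample, protein_id, intra_cv, inter_cv (percent).
#' @export
qc_cv <- function(replicates) {
  need <- c("qc_sample", "plate", "protein_id", "npx")
  if (!all(need %in% names(replicates)))
    stop("replicate table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  replicates$lin <- 2^replicates$npx
  out <- NULL
  for (qs in unique(replicates$qc_sample)) {
    for (p in unique(replicates$protein_id)) {
      d <- replicates[replicates$qc_sample == qs & replicates$protein_id == p, ]
      if (!nrow(d)) next
      per_plate <- split(d$lin, d$plate)
      if (any(lengths(per_plate) < 2))
        stop("QC sample '", qs, "' has a plate with < 2 replicates for protein '",
             p, "'", call. = FALSE)
      intra <- mean(vapply(per_plate, function(x) 100 * stats::sd(x) / mean(x),
                           numeric(1)))
      if (length(per_plate) < 2)
        stop("QC sample '", qs, "' measured on < 2 plates for protein '", p,
             "' (inter-assay CV needs >= 2 plates)", call. = FALSE)
      pm <- vapply(per_plate, mean, numeric(1))
      inter <- 100 * stats::sd(pm) / mean(pm)
      out <- rbind(out, data.frame(qc_sample = qs, protein_id = p,
                                   intra_cv = intra, inter_cv = inter,
                                   stringsAsFactors = FALSE))
    }
  }
  out
}
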