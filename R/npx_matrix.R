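#' NPX abundance matrix with per-protein detection limits
#'
#' Container for a samples-by-proteins matrix of NPX values (Olink's
#' normalized protein expression, a log2-scale relative abundance unit:
#' a difference of 1 NPX is roughly a 2-fold concentration difference)
#' together with each assay's limit of detection (LOD) on the same scale.
#'
#' @param values numeric matrix, rows = samples, columns = proteins. Row
#'   and column names are required and must be unique; they become the
#'   sample and protein identifiers.
#' @param lod numeric vector of per-protein LODs in NPX units, one per
#'   column of \code{values} (recycled if length 1). \code{-Inf} means
#'   "always detected". Named vectors are matched to protein IDs.
#' @param aliases optional named character vector mapping protein
#'   (assay-level) IDs to gene-symbol aliases; the same symbol may back
#'   several assay IDs when a protein is measured on two panels.
#'
#' @return an object of class \code{npx_matrix}: a list with elements
#'   \code{values}, \code{lod}, \code{aliases}.
#' @export
npx_matrix <- function(values, lod = rep(-Inf, ncol(values)), aliases = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must carry sample IDs as rownames and protein IDs as colnames",
         call. = FALSE)
  if (anyDuplicated(rownames(values)))
    stop("duplicate sample IDs: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(colnames(values)))
    stop("duplicate protein IDs: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "),
         call. = FALSE)
  if (length(lod) == 1L) lod <- rep(lod, ncol(values))
  if (!is.null(names(lod))) {
    missing_lod <- setdiff(colnames(values), names(lod))
    if (length(missing_lod))
      stop("LOD missing for proteins: ", paste(missing_lod, collapse = ", "),
           call. = FALSE)
    lod <- lod[colnames(values)]
  } else if (length(lod) != ncol(values)) {
    stop("'lod' must have one entry per protein", call. = FALSE)
  }
  if (any(is.na(lod)))
    stop("'lod' must not contain NA (use -Inf for always-detected)", call. = FALSE)
  names(lod) <- colnames(values)
  structure(list(values = values, lod = lod, aliases = aliases),
            class = "npx_matrix")
}

#' @export
print.npx_matrix <- function(x, ...) {
  cat(sprintf("<npx_matrix> %d samples x %d proteins (NPX, log2 scale)\n",
              nrow(x$values), ncol(x$values)))
  cat(sprintf("  LOD defined for all proteins; %d proteins always detected (LOD = -Inf)\n",
              sum(is.infinite(x$lod) & x$lod < 0)))
  invisible(x)
}

#' @export
dim.npx_matrix <- function(x) dim(x$values)

sample_ids <- function(npx) rownames(npx$values)
protein_ids <- function(npx) colnames(npx$values)

#' Subset an NPX matrix by samples and/or proteins
#'
#' @param x an \code{npx_matrix}.
#' @param i sample selector (IDs, indices, or logical).
#' @param j protein selector.
#' @param ... unused.
#' @return an \code{npx_matrix}.
#' @export
`[.npx_matrix` <- function(x, i, j, ...) {
  v <- x$values
  if (missing(i)) i <- seq_len(nrow(v))
  if (missing(j)) j <- seq_len(ncol(v))
  v <- v[i, j, drop = FALSE]
  npx_matrix(v, x$lod[colnames(v)], x$aliases)
}

#' Validate a sample-metadata table against an NPX matrix
#'
#' Checks the contract that every analysis function relies on: one
#' metadata row per NPX sample, in the same order, with group labels from
#' \{CON, FTD, AD\} for every non-QC sample and sane covariate ranges.
#'
#' @param meta a data.frame with at least \code{sample_id} and
#'   \code{group}; recognised columns are \code{sample_id, subject_id,
#'   group, subtype, mutation_status, age, sex, mmse, ftld_cdr,
#'   cdr_rater, plate, round, is_bridging, is_qc, ad_copathology}.
#' @param npx optional \code{npx_matrix} to align against.
#' @return \code{meta}, invisibly, after validation.
#' @export
validate_metadata <- function(meta, npx = NULL) {
  if (!is.data.frame(meta) || !all(c("sample_id", "group") %in% names(meta)))
    stop("metadata must be a data.frame with 'sample_id' and 'group' columns",
         call. = FALSE)
  if (anyDuplicated(meta$sample_id))
    stop("duplicate sample_id in metadata: ",
         paste(unique(meta$sample_id[duplicated(meta$sample_id)]), collapse = ", "),
         call. = FALSE)
  is_qc <- if ("is_qc" %in% names(meta)) isTRUE_vec(meta$is_qc) else rep(FALSE, nrow(meta))
  bad_group <- !is_qc & (is.na(meta$group) | !meta$group %in% c("CON", "FTD", "AD"))
  if (any(bad_group))
    stop("unknown group label for non-QC sample(s): ",
         paste(utils::head(meta$sample_id[bad_group], 5), collapse = ", "),
         call. = FALSE)
  if ("age" %in% names(meta) && any(!is.na(meta$age) & meta$age <= 0))
    stop("age must be > 0 where present", call. = FALSE)
  if ("mmse" %in% names(meta) &&
      any(!is.na(meta$mmse) & (meta$mmse < 0 | meta$mmse > 30)))
    stop("mmse must be in [0, 30] where present", call. = FALSE)
  if (!is.null(npx)) {
    only_npx <- setdiff(sample_ids(npx), meta$sample_id)
    only_meta <- setdiff(meta$sample_id, sample_ids(npx))
    if (length(only_npx))
      stop("samples present in NPX but not metadata: ",
           paste(utils::head(only_npx, 5), collapse = ", "), call. = FALSE)
    if (length(only_meta))
      stop("samples present in metadata but not NPX: ",
           paste(utils::head(only_meta, 5), collapse = ", "), call. = FALSE)
  }
  invisible(meta)
}

isTRUE_vec <- function(x) !is.na(x) & (x == TRUE | x == "TRUE" | x == 1)
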