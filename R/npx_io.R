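# Reading and writing the tabular formats the pipeline touches.
# CSV dialect everywhere: comma-separated, UTF-8, "." decimal, header row
# required, empty string = missing. Numbers are written with >= 15
# significant digits so write -> read round-trips to machine precision.

fmt_num <- function(x) {
  out <- formatC(x, digits = 15, format = "g")
  out[is.na(x)] <- ""
  out
}

write_csv_plain <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  out <- df
  out[num] <- lapply(df[num], fmt_num)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "",
                   fileEncoding = "UTF-8")
}

read_csv_plain <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  utils::read.csv(path, check.names = FALSE, na.strings = "",
                  fileEncoding = "UTF-8", stringsAsFactors = FALSE)
}

#' Read a cohort from NPX, metadata and LOD CSV files
#'
#' The NPX file is wide (first column \code{sample_id}, one column per
#' protein) or long Olink-style (\code{sample_id, protein_id, npx}), in
#' which case it is pivoted to wide; duplicate sample-by-protein entries
#' in a long file are an error, never averaged, because silent averaging
#' hides plate mix-ups. Samples present in only one of the NPX and
#' metadata files are an error. Column (protein) order is preserved.
#'
#' @param npx_path path to the NPX CSV.
#' @param meta_path path to the sample metadata CSV.
#' @param lod_path path to the LOD CSV (\code{protein_id, lod}).
#' @return a list with elements \code{npx} (an \code{\link{npx_matrix}})
#'   and \code{meta} (data.frame, rows aligned to the NPX sample order).
#' @export
read_cohort <- function(npx_path, meta_path, lod_path) {
  raw <- read_csv_plain(npx_path)
  if (!nrow(raw)) stop("empty NPX file: ", npx_path, call. = FALSE)
  long <- all(c("sample_id", "protein_id", "npx") %in% names(raw)) &&
    ncol(raw) <= 4L
  if (long) {
    key <- paste(raw$sample_id, raw$protein_id, sep = "\r")
    if (anyDuplicated(key))
      stop("duplicate sample x protein entries in long NPX file: ",
           paste(utils::head(unique(gsub("\r", " / ", key[duplicated(key)])), 3),
                 collapse = "; "), call. = FALSE)
    sids <- unique(raw$sample_id)
    pids <- unique(raw$protein_id)
    vals <- matrix(NA_real_, length(sids), length(pids),
                   dimnames = list(sids, pids))
    vals[cbind(match(raw$sample_id, sids), match(raw$protein_id, pids))] <-
      as.numeric(raw$npx)
  } else {
    if (names(raw)[1] != "sample_id")
      stop("wide NPX file must have 'sample_id' as its first column",
           call. = FALSE)
    vals <- as.matrix(raw[, -1, drop = FALSE])
    bad <- which(!vapply(raw[-1], is.numeric, logical(1)))
    if (length(bad)) {
      # locate first offending cell for the error message
      col <- names(raw)[-1][bad[1]]
      row <- which(is.na(suppressWarnings(as.numeric(raw[[col]]))) &
                     !is.na(raw[[col]]))[1]
      stop(sprintf("non-numeric NPX cell at sample '%s', protein '%s'",
                   raw$sample_id[row], col), call. = FALSE)
    }
    storage.mode(vals) <- "double"
    rownames(vals) <- as.character(raw$sample_id)
  }

  lod_df <- read_csv_plain(lod_path)
  if (!all(c("protein_id", "lod") %in% names(lod_df)))
    stop("LOD file must have columns 'protein_id' and 'lod'", call. = FALSE)
  lod <- as.numeric(lod_df$lod)
  names(lod) <- lod_df$protein_id

  meta <- read_csv_plain(meta_path)
  npx <- npx_matrix(vals, lod)
  validate_metadata(meta, npx)
  meta <- meta[match(sample_ids(npx), meta$sample_id), , drop = FALSE]
  rownames(meta) <- NULL
  list(npx = npx, meta = meta)
}

#' Write a cohort to NPX, metadata, LOD (and optionally truth) CSVs
#'
#' @param cohort a list with \code{npx} and \code{meta} (and optionally
#'   \code{truth}), e.g. from \code{\link{simulate_cohort}} or
#'   \code{\link{read_cohort}}.
#' @param dir output directory, created if absent.
#' @param prefix file-name prefix.
#' @return invisible named vector of written paths.
#' @export
write_cohort <- function(cohort, dir, prefix = "cohort") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  npx <- cohort$npx
  paths <- c(
    npx = file.path(dir, paste0(prefix, "_npx.csv")),
    meta = file.path(dir, paste0(prefix, "_meta.csv")),
    lod = file.path(dir, paste0(prefix, "_lod.csv"))
  )
  wide <- data.frame(sample_id = sample_ids(npx), npx$values,
                     check.names = FALSE, stringsAsFactors = FALSE)
  write_csv_plain(wide, paths[["npx"]])
  write_csv_plain(cohort$meta, paths[["meta"]])
  write_csv_plain(data.frame(protein_id = protein_ids(npx), lod = npx$lod,
                             stringsAsFactors = FALSE), paths[["lod"]])
  if (!is.null(cohort$truth)) {
    paths <- c(paths, truth = file.path(dir, paste0(prefix, "_truth.csv")))
    write_csv_plain(cohort$truth, paths[["truth"]])
  }
  invisible(paths)
}

#' Write result tables plus a JSON run manifest
#'
#' One CSV per table; a manifest records the inputs, a hash of the run
#' configuration, the seed, and package/R versions, so a run can be
#' audited and reproduced.
#'
#' @param tables named list of data.frames (may be empty).
#' @param out_dir output directory.
#' @param config optional run configuration list (hashed into manifest).
#' @param seed optional master seed recorded in the manifest.
#' @return the manifest, invisibly.
#' @export
write_results <- function(tables = list(), out_dir, config = NULL, seed = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create output dir: ", out_dir, call. = FALSE)
  if (length(tables) && is.null(names(tables)))
    stop("'tables' must be a named list", call. = FALSE)
  files <- character(0)
  for (nm in names(tables)) {
    p <- file.path(out_dir, paste0(nm, ".csv"))
    write_csv_plain(as.data.frame(tables[[nm]]), p)
    files[nm] <- basename(p)
  }
  manifest <- list(
    files = as.list(files),
    config_hash = if (is.null(config)) NULL else config_hash(config),
    seed = seed,
    versions = list(npxpanel = as.character(utils::packageVersion("npxpanel")),
                    R = paste(R.version$major, R.version$minor, sep = "."))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(manifest)
}

# Stable hash of a configuration tree: serialize to canonical JSON, then
# accumulate a simple polynomial rolling hash (no digest dependency).
config_hash <- function(config) {
  s <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA, null = "null")
  bytes <- utf8ToInt(as.character(s))
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2^31
  sprintf("%08x", as.integer(h))
}

#' Serialize a fitted panel model to JSON
#'
#' Schema: \code{\{markers: [\{protein_id, coefficient, mean, sd\}],
#' intercept, covariates: [\{name, coefficient\}], trained_on, penalty,
#' seed\}}. Everything needed to score a new cohort (including the
#' training standardization parameters) is stored, so a written panel
#' predicts identically after reading back.
#'
#' @param panel a \code{panel_model} (see \code{\link{ridge_refit}}).
#' @param path output JSON path.
#' @return \code{path}, invisibly.
#' @export
write_panel_json <- function(panel, path) {
  stopifnot(inherits(panel, "panel_model"))
  obj <- list(
    markers = lapply(seq_along(panel$markers), function(i) list(
      protein_id = panel$markers[i],
      coefficient = panel$coefficients[i],
      mean = panel$standardization$mean[i],
      sd = panel$standardization$sd[i]
    )),
    intercept = panel$intercept,
    covariates = lapply(seq_along(panel$covariate_terms), function(i) list(
      name = names(panel$covariate_terms)[i],
      coefficient = panel$covariate_terms[[i]]
    )),
    trained_on = panel$trained_on,
    penalty = panel$penalty,
    seed = panel$seed
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Read a panel model back from JSON
#'
#' @param path JSON path written by \code{\link{write_panel_json}}.
#' @return a \code{panel_model}.
#' @export
read_panel_json <- function(path) {
  obj <- jsonlite::read_json(path)
  markers <- vapply(obj$markers, function(m) m$protein_id, character(1))
  new_panel_model(
    markers = markers,
    coefficients = vapply(obj$markers, function(m) as.numeric(m$coefficient), numeric(1)),
    intercept = as.numeric(obj$intercept),
    covariate_terms = stats::setNames(
      lapply(obj$covariates, function(cv) as.numeric(cv$coefficient)),
      vapply(obj$covariates, function(cv) cv$name, character(1))
    ),
    standardization = list(
      mean = stats::setNames(vapply(obj$markers, function(m) as.numeric(m$mean), numeric(1)), markers),
      sd = stats::setNames(vapply(obj$markers, function(m) as.numeric(m$sd), numeric(1)), markers)
    ),
    penalty = as.numeric(obj$penalty),
    trained_on = obj$trained_on %||% NA_character_,
    seed = obj$seed %||% NA_integer_
  )
}
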