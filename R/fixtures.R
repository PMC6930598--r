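#' Packaged lipophilicity tables for the 26-compound isoxazolone series
#'
#' Three tables of lipophilicity estimates for the same 26 isoxazolo[3,4-b]
#' pyridin-3(1H)-one derivatives, transcribed at printed precision:
#'
#' * `software`: 13 log P estimates from commercial and free calculators
#'   (atom-based, fragment-contribution, property-based and hybrid
#'   algorithms), 26 x 13.
#' * `dft`: 6 log P estimates from DFT solvation free-energy differences
#'   (B3LYP, CAM-B3LYP, wB97XD, PBE0 functionals with several basis sets),
#'   26 x 6.
#' * `chromatographic`: 12 experimentally derived indices, 26 x 12 - RP-TLC
#'   intercepts (R_M0), slopes (m), C0, mean R_M and first principal
#'   component on C8- and C18-modified silica, gradient-HPLC log k_w, and
#'   MEKC log k.
#'
#' Values are stored exactly as printed, including anomalies (e.g. the
#' logPV Spartan value of 4.72 for compound 12, in contradiction with every
#' other estimate for that methylsulfonyl derivative); anomalies are data,
#' not transcription errors. Files are integrity-checked on load.
#'
#' @param which One of `"software"`, `"dft"`, `"chromatographic"`, or
#'   `"all"` (default) for a named list of the three tibbles.
#' @return A tibble with a `compound` id column (1-26), or a named list of
#'   the three tibbles when `which = "all"`.
#' @seealso [measure_metadata()], [assemble_matrix()]
#' @examples
#' lipo_fixtures("chromatographic")
#' @export
lipo_fixtures <- function(which = c("all", "software", "dft", "chromatographic")) {
  which <- match.arg(which)
  files <- c(
    software        = "software_logp.csv",
    dft             = "dft_logp.csv",
    chromatographic = "chromatographic_indices.csv"
  )
  if (which == "all") {
    return(lapply(setNames(nm = names(files)), function(w) lipo_fixtures(w)))
  }
  path <- fixture_path(files[[which]])
  check_fixture_checksum(path)
  tbl <- tibble::as_tibble(read.csv(path, check.names = FALSE))
  stopifnot(identical(tbl$compound, 1:26), !anyNA(tbl))
  tbl
}

fixture_path <- function(file) {
  path <- system.file("extdata", file, package = "liporank")
  if (!nzchar(path)) abort(paste0("fixture file not found: ", file))
  path
}

# md5 digests of the shipped fixture files, frozen at transcription time
.fixture_md5 <- c(
  chromatographic_indices.csv = "8c6d8d19881d3ab2f00ce13b8f4ae058",
  dft_logp.csv                = "a9abb3482224d67d9f3be8c4832f9437",
  measure_meta.csv            = "aa40a998d6603301b57601a6d3e26fbc",
  software_logp.csv           = "e307ff49829a8e7cfabf38eb569c2cc7"
)

check_fixture_checksum <- function(path) {
  expected <- .fixture_md5[[basename(path)]]
  observed <- unname(tools::md5sum(path))
  if (!identical(observed, expected)) {
    abort(paste0(
      "fixture checksum failure for ", basename(path),
      ": expected ", expected, ", got ", observed
    ))
  }
  invisible(TRUE)
}

#' Measure metadata: source technique and descriptor class of each measure
#'
#' One row per lipophilicity measure in the packaged tables, carrying the
#' source technique and the nine-level descriptor-class factor used in the
#' ANOVA decomposition of cross-validated SRD scores: computational
#' estimates grouped by algorithm family (atom-based `Comp_A`,
#' fragment-contribution `Comp_F`, property-based `Comp_P`, hybrid
#' `Comp_M`, DFT-based `Comp_DFT`) and chromatographic indices grouped by
#' technique (`TLC_C8`, `TLC_C18`, `HPLC_C18`, `MEKC`).
#'
#' @return A tibble with columns `measure_id`, `source`, `anova_class`.
#' @export
measure_metadata <- function() {
  path <- fixture_path("measure_meta.csv")
  check_fixture_checksum(path)
  tibble::as_tibble(read.csv(path, stringsAsFactors = FALSE))
}

#' Assemble a compounds-by-measures lipophilicity matrix
#'
#' Joins one or more per-technique tables (each with a `compound` id column)
#' into a single compounds x measures table with per-measure metadata
#' attached, the common input of [srd_scores()], [sevenfold_cv()],
#' [pearson_matrix()] and [pca_overview()]. With the packaged fixtures the
#' result is the full 26 x 31 panel.
#'
#' @param tables A data frame or a (possibly named) list of data frames,
#'   each with a `compound` column and numeric measure columns. Defaults to
#'   all three packaged fixture tables.
#' @param meta Measure metadata as from [measure_metadata()]; rows are
#'   matched to columns by `measure_id`. Measures without metadata are kept
#'   with `NA` class.
#' @param na_action `"error"` (default) refuses missing cells; `"drop"`
#'   removes compounds with any missing value.
#' @return A `lipo_matrix`: a tibble (`compound` + one column per measure)
#'   with `meta` and `pretreatment` (`"RAW"`) attributes.
#' @examples
#' m <- assemble_matrix()
#' dim(m) # 26 compounds, 1 id column + 31 measures
#' @export
assemble_matrix <- function(tables = lipo_fixtures(), meta = measure_metadata(),
                            na_action = c("error", "drop")) {
  na_action <- match.arg(na_action)
  if (is.data.frame(tables)) tables <- list(tables)
  tables <- lapply(tables, function(t) {
    if (!"compound" %in% names(t)) abort("every table needs a `compound` column")
    tibble::as_tibble(t)
  })
  ids <- lapply(tables, function(t) sort(t$compound))
  if (length(unique(ids)) > 1L) {
    all_ids <- sort(unique(unlist(ids)))
    offenders <- purrr::map_chr(tables, function(t) {
      missing <- setdiff(all_ids, t$compound)
      if (length(missing)) paste(missing, collapse = ",") else "-"
    })
    abort(paste0(
      "compound sets do not align across tables; missing ids per table: ",
      paste(offenders, collapse = " | ")
    ))
  }
  out <- purrr::reduce(tables, dplyr::inner_join, by = "compound")
  if (anyDuplicated(out$compound)) abort("duplicate compound ids")
  if (anyNA(out)) {
    if (na_action == "error") {
      abort("missing values in assembled matrix (set na_action = \"drop\" to remove compounds)")
    }
    out <- out[stats::complete.cases(out), ]
  }
  measure_ids <- setdiff(names(out), "compound")
  meta <- dplyr::left_join(tibble::tibble(measure_id = measure_ids), meta,
                           by = "measure_id")
  new_lipo_matrix(out, meta, "RAW")
}

new_lipo_matrix <- function(tbl, meta, pretreatment) {
  structure(tbl,
    meta = meta, pretreatment = pretreatment,
    class = c("lipo_matrix", class(tibble::as_tibble(tbl)))
  )
}

#' @export
print.lipo_matrix <- function(x, ...) {
  cat("<lipo_matrix> ", nrow(x), " compounds x ", ncol(x) - 1L,
      " measures, pretreatment: ", attr(x, "pretreatment"), "\n", sep = "")
  NextMethod()
}

measure_values <- function(m) {
  as.matrix(m[setdiff(names(m), "compound")])
}

#' Column-wise pretreatment of a lipophilicity matrix
#'
#' Brings measures expressed on different scales to a common one before SRD
#' analysis. Three standard pretreatments are supported, applied per
#' measure (column):
#'
#' * `STD`: standardization to zero mean and unit standard deviation;
#' * `IS`: interval scaling to the range `[0, 1]`;
#' * `RNK`: rank transformation with ties replaced by average ranks.
#'
#' `STD` and `IS` refuse constant columns (their scale is undefined); `RNK`
#' accepts them.
#'
#' @param m A `lipo_matrix` from [assemble_matrix()] (or any data frame with
#'   a `compound` column and numeric measures).
#' @param kind `"STD"`, `"IS"`, or `"RNK"`.
#' @return A `lipo_matrix` with the `pretreatment` attribute updated.
#' @export
pretreat <- function(m, kind = c("STD", "IS", "RNK")) {
  kind <- match.arg(kind)
  if (!inherits(m, "lipo_matrix")) m <- assemble_matrix(m, measure_metadata())
  vals <- measure_values(m)
  if (kind %in% c("STD", "IS")) {
    rng <- apply(vals, 2, function(x) diff(range(x)))
    if (any(rng < 1e-300)) {
      abort(paste0("constant column(s) under ", kind, ": ",
                   paste(colnames(vals)[rng < 1e-300], collapse = ", ")))
    }
  }
  out <- switch(kind,
    STD = scale(vals),
    IS  = apply(vals, 2, function(x) (x - min(x)) / diff(range(x))),
    RNK = apply(vals, 2, rank_with_ties)
  )
  tbl <- tibble::as_tibble(as.data.frame(out))
  tbl <- dplyr::bind_cols(tibble::tibble(compound = m$compound), tbl)
  new_lipo_matrix(tbl, attr(m, "meta"), kind)
}
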