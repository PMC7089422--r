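# Reading and writing the pipeline's delimited formats: GWAS summary
# statistics (with a configurable column map for external dialects), square
# LD matrices, PLINK-style clump tables and harmonised data.

.ss_cols <- c(snp = "SNP", chr = "CHR", bp = "BP", ea = "EA", oa = "OA",
              eaf = "EAF", beta = "BETA", se = "SE", p = "P", n = "N",
              info = "INFO")

#' Write summary statistics as TSV
#'
#' Standard column set: SNP, CHR, BP, EA, OA, EAF, BETA, SE, P, N, INFO.
#'
#' @param stats Summary-statistics tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_summary_stats <- function(stats, path) {
  out <- stats[, names(.ss_cols)]
  names(out) <- unname(.ss_cols)
  readr::write_tsv(out, path)
  invisible(path)
}

#' Read summary statistics from a delimited file
#'
#' Accepts the package's own TSV dialect by default; `column_map` renames
#' external headers (e.g. consortium exports) onto the internal schema:
#' a named character vector `c(snp = "markername", beta = "beta", ...)`.
#' Missing optional columns (`info`, `n`) are filled with defaults;
#' `log10_p` is recomputed from beta/se downstream when needed.
#'
#' @param path Input path (any delimiter readr can guess; TSV expected).
#' @param column_map Named character vector mapping internal names to file
#'   headers. Defaults to the package's own header set.
#' @param trait_name Value for the `trait` column.
#' @return Summary-statistics tibble.
#' @export
read_summary_stats <- function(path, column_map = NULL, trait_name = NA) {
  map <- if (is.null(column_map)) .ss_cols else column_map
  raw <- readr::read_tsv(path, show_col_types = FALSE)
  missing <- setdiff(unname(map[c("snp", "ea", "oa", "beta", "se")]),
                     names(raw))
  if (length(missing)) {
    abort(paste("input lacks required columns:",
                paste(missing, collapse = ", ")))
  }
  out <- tibble::tibble(
    snp = as.character(raw[[map["snp"]]]),
    chr = if (!is.na(map["chr"]) && map["chr"] %in% names(raw)) {
      raw[[map["chr"]]]
    } else NA_integer_,
    bp = if (!is.na(map["bp"]) && map["bp"] %in% names(raw)) {
      raw[[map["bp"]]]
    } else NA_integer_,
    ea = toupper(raw[[map["ea"]]]), oa = toupper(raw[[map["oa"]]]),
    eaf = if (!is.na(map["eaf"]) && map["eaf"] %in% names(raw)) {
      raw[[map["eaf"]]]
    } else NA_real_,
    beta = raw[[map["beta"]]], se = raw[[map["se"]]],
    p = if (!is.na(map["p"]) && map["p"] %in% names(raw)) {
      raw[[map["p"]]]
    } else 2 * pnorm(-abs(raw[[map["beta"]]] / raw[[map["se"]]])),
    n = if (!is.na(map["n"]) && map["n"] %in% names(raw)) {
      as.integer(raw[[map["n"]]])
    } else NA_integer_,
    info = if (!is.na(map["info"]) && map["info"] %in% names(raw)) {
      raw[[map["info"]]]
    } else 1,
    trait = trait_name)
  out$log10_p <- .log10p(out[, c("beta", "se")])
  out
}

#' Write / read an LD matrix as square TSV
#'
#' Square matrix with SNP ids as the header row and first column.
#'
#' @param ld An `ld_matrix`.
#' @param path File path.
#' @return `path` / an `ld_matrix`.
#' @export
write_ld_matrix <- function(ld, path) {
  df <- tibble::as_tibble(unclass(ld), .name_repair = "minimal")
  df <- dplyr::bind_cols(tibble::tibble(SNP = rownames(ld)), df)
  readr::write_tsv(df, path)
  invisible(path)
}

#' @rdname write_ld_matrix
#' @export
read_ld_matrix <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  ids <- df$SNP
  m <- as.matrix(df[, -1])
  rownames(m) <- ids
  class(m) <- c("ld_matrix", class(m))
  m
}

#' Write a clump table (PLINK-style)
#'
#' One row per index SNP: INDEX_SNP, CHR, BP, P, N_CLUMPED, MEMBERS (comma
#' separated absorbed SNPs).
#'
#' @param instruments Output of [ld_clump()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_clumped <- function(instruments, path) {
  members <- attr(instruments, "members") %||%
    setNames(rep(list(character(0)), nrow(instruments)), instruments$snp)
  out <- tibble::tibble(
    INDEX_SNP = instruments$snp, CHR = instruments$chr,
    BP = instruments$bp, P = instruments$p,
    N_CLUMPED = vapply(instruments$snp,
                       function(s) length(members[[s]]), 1L),
    MEMBERS = vapply(instruments$snp, function(s) {
      paste(members[[s]], collapse = ",")
    }, ""))
  readr::write_tsv(out, path)
  invisible(path)
}

#' Write / read harmonised data as TSV
#'
#' One row per SNP with all exposure beta/se column pairs, the outcome pair
#' and the provenance flag; exposure names and the drop log are carried in a
#' header comment-free sidecar of columns, so the file round-trips through
#' [read_harmonised()].
#'
#' @param dat An `mr_harmonised`.
#' @param path File path.
#' @return `path` / an `mr_harmonised` (the drop log is not persisted).
#' @export
write_harmonised <- function(dat, path) {
  readr::write_tsv(tibble::as_tibble(dat), path)
  invisible(path)
}

#' @rdname write_harmonised
#' @export
read_harmonised <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE)
  exposures <- sub("^beta_", "",
                   setdiff(grep("^beta_", names(out), value = TRUE),
                           "beta_outcome"))
  structure(out, exposures = exposures,
            dropped = tibble::tibble(snp = character(0),
                                     reason = character(0)),
            retention = NA_real_,
            class = c("mr_harmonised", class(out)))
}
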