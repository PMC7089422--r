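# Harmonisation of exposure and outcome summary statistics to a shared
# effect allele, with strand resolution, palindromic handling and LD proxies.

.is_palindromic <- function(ea, oa) ea == .COMP[oa]

.valid_alleles <- function(...) all(unlist(list(...)) %in% .ACGT)

#' Align one outcome row to an exposure row's effect allele
#'
#' Resolution order: direct allele match (unchanged); swapped effect/other
#' allele (negate beta, complement eaf); strand complement, possibly plus
#' swap; palindromic A/T-or-C/G SNPs are oriented by allele-frequency
#' agreement when both frequencies are outside the ambiguity window, and
#' dropped otherwise; incompatible allele pairs are dropped.
#'
#' @param exposure_row,outcome_row One-row data frames (or lists) with at
#'   least `ea`, `oa`, `beta`, `eaf`; the same SNP in the two studies.
#' @param palindromic_window Allele-frequency interval within which a
#'   palindromic SNP cannot be oriented (default `c(0.42, 0.58)`).
#' @return List with `outcome_row` (aligned, or `NULL` when dropped) and
#'   `action`: one of `"direct"`, `"flipped"`, `"strand_flipped"`,
#'   `"strand_flipped_swapped"`, `"dropped:palindromic_ambiguous"`,
#'   `"dropped:incompatible_alleles"`.
#' @export
align_alleles <- function(exposure_row, outcome_row,
                          palindromic_window = c(0.42, 0.58)) {
  ex <- as.list(exposure_row); ou <- as.list(outcome_row)
  if (!.valid_alleles(ex$ea, ex$oa, ou$ea, ou$oa)) {
    abort("malformed alleles (must be one of A, C, G, T)")
  }
  flip <- function(row) {
    row$beta <- -row$beta
    if (!is.null(row$eaf) && !is.na(row$eaf)) row$eaf <- 1 - row$eaf
    tmp <- row$ea; row$ea <- row$oa; row$oa <- tmp
    row
  }
  done <- function(row, action) {
    # relabel to the exposure orientation so downstream joins are trivial
    row$ea <- ex$ea; row$oa <- ex$oa
    list(outcome_row = tibble::as_tibble(row), action = action)
  }
  if (.is_palindromic(ex$ea, ex$oa)) {
    same_set <- setequal(c(ou$ea, ou$oa), c(ex$ea, ex$oa))
    if (!same_set) {
      return(list(outcome_row = NULL,
                  action = "dropped:incompatible_alleles"))
    }
    if (is.null(ex$eaf) || is.null(ou$eaf) ||
        is.na(ex$eaf) || is.na(ou$eaf) ||
        (ex$eaf >= palindromic_window[1] & ex$eaf <= palindromic_window[2]) ||
        (ou$eaf >= palindromic_window[1] & ou$eaf <= palindromic_window[2])) {
      return(list(outcome_row = NULL,
                  action = "dropped:palindromic_ambiguous"))
    }
    # frequency agreement decides orientation; allele labels cannot
    same_side <- (ex$eaf - 0.5) * (ou$eaf - 0.5) > 0
    if (same_side) return(done(ou, "direct"))
    return(done(flip(ou), "flipped"))
  }
  if (ou$ea == ex$ea && ou$oa == ex$oa) return(done(ou, "direct"))
  if (ou$ea == ex$oa && ou$oa == ex$ea) return(done(flip(ou), "flipped"))
  cea <- unname(.COMP[ou$ea]); coa <- unname(.COMP[ou$oa])
  if (cea == ex$ea && coa == ex$oa) return(done(ou, "strand_flipped"))
  if (cea == ex$oa && coa == ex$ea) {
    return(done(flip(ou), "strand_flipped_swapped"))
  }
  list(outcome_row = NULL, action = "dropped:incompatible_alleles")
}

# label-only alignment for rows known to share a strand (same-study traits)
.align_label <- function(ref_row, row) {
  if (row$ea == ref_row$ea && row$oa == ref_row$oa) return(row)
  if (row$ea == ref_row$oa && row$oa == ref_row$ea) {
    row$beta <- -row$beta
    if (!is.null(row$eaf) && !is.na(row$eaf)) row$eaf <- 1 - row$eaf
    return(row)
  }
  cea <- unname(.COMP[row$ea]); coa <- unname(.COMP[row$oa])
  if (cea == ref_row$ea && coa == ref_row$oa) return(row)
  if (cea == ref_row$oa && coa == ref_row$ea) {
    row$beta <- -row$beta
    if (!is.null(row$eaf) && !is.na(row$eaf)) row$eaf <- 1 - row$eaf
    return(row)
  }
  NULL
}

#' Find an LD proxy for a SNP missing from the outcome statistics
#'
#' Among outcome SNPs with r-squared strictly above `r2_min` against the
#' target (in the signed LD reference), returns the one with maximal
#' r-squared; ties go to the smallest base-pair distance, then lexicographic
#' SNP id. The target itself (r-squared 1) wins when present.
#'
#' @param target_snp SNP id.
#' @param target_bp Base-pair position of the target (for tie-breaking);
#'   may be `NA`.
#' @param outcome_stats Summary-stat tibble to search.
#' @param ld Signed `ld_matrix` covering the target and candidates.
#' @param r2_min Strict lower bound on r-squared (default 0.8).
#' @return List `(snp, r, r2)` or `NULL` when no candidate qualifies (a
#'   target absent from the LD reference also returns `NULL`, with a message).
#' @export
find_proxy <- function(target_snp, outcome_stats, ld, r2_min = 0.8,
                       target_bp = NA) {
  if (!target_snp %in% rownames(ld)) {
    inform(paste0("proxy search: ", target_snp, " absent from LD reference"))
    return(NULL)
  }
  cand <- intersect(outcome_stats$snp, colnames(ld))
  if (!length(cand)) return(NULL)
  r <- ld[target_snp, cand]
  r2 <- r^2
  ok <- r2 > r2_min
  if (!any(ok)) return(NULL)
  cand <- cand[ok]; r <- r[ok]; r2 <- r2[ok]
  bp <- outcome_stats$bp[match(cand, outcome_stats$snp)]
  dist <- abs(bp - target_bp)
  dist[is.na(dist)] <- Inf
  ord <- order(-r2, dist, cand)
  list(snp = cand[ord[1]], r = unname(r[ord[1]]), r2 = unname(r2[ord[1]]))
}

#' Harmonise exposures and outcome into a multivariable effect matrix
#'
#' Aligns every SNP in `snps` to a single effect allele across all exposure
#' traits and the outcome. Every union SNP must be present in each trait's
#' *full* summary statistics (an error otherwise — instruments for one trait
#' need betas for all traits). Outcome rows are matched directly, or through
#' an LD proxy (r-squared > `proxy_r2`, oriented by the signed LD r), or the
#' SNP is dropped with a recorded reason.
#'
#' @param exposure_stats Named list of full summary-stat tibbles.
#' @param snps Character vector: the instrument union.
#' @param outcome_stats Outcome summary-stat tibble.
#' @param ld Optional signed `ld_matrix` (enables proxy substitution).
#' @param proxy_r2 Strict r-squared bound for proxies (default 0.8).
#' @param palindromic_window See [align_alleles()].
#' @return An `mr_harmonised` tibble: snp, chr, bp, ea, oa, per-trait
#'   `beta_<trait>` / `se_<trait>` columns, `beta_outcome`, `se_outcome`,
#'   `provenance`. Attributes: `exposures`, `dropped` (tibble snp/reason),
#'   `retention` (J / |union|).
#' @export
harmonise_mvmr <- function(exposure_stats, snps, outcome_stats, ld = NULL,
                           proxy_r2 = 0.8,
                           palindromic_window = c(0.42, 0.58)) {
  stopifnot(is.list(exposure_stats), length(exposure_stats) >= 1)
  traits <- names(exposure_stats)
  for (tr in traits) {
    missing <- setdiff(snps, exposure_stats[[tr]]$snp)
    if (length(missing)) {
      abort(paste0("full summary statistics for trait '", tr,
                   "' lack required SNP(s): ",
                   paste(head(missing, 5), collapse = ", ")))
    }
  }
  ref <- exposure_stats[[1]][match(snps, exposure_stats[[1]]$snp), ]
  rows <- list(); dropped <- list()
  for (i in seq_along(snps)) {
    s <- snps[i]
    ref_row <- ref[i, ]
    row <- list(snp = s, chr = ref_row$chr, bp = ref_row$bp,
                ea = ref_row$ea, oa = ref_row$oa)
    row[[paste0("beta_", traits[1])]] <- ref_row$beta
    row[[paste0("se_", traits[1])]] <- ref_row$se
    # exposures are assumed strand-consistent (one study), so cross-exposure
    # alignment matches allele labels without the palindromic frequency rule
    bad <- NULL
    for (tr in traits[-1]) {
      er <- exposure_stats[[tr]][exposure_stats[[tr]]$snp == s, ][1, ]
      al <- .align_label(ref_row, er)
      if (is.null(al)) {
        bad <- "incompatible_alleles"
        break
      }
      row[[paste0("beta_", tr)]] <- al$beta
      row[[paste0("se_", tr)]] <- er$se
    }
    if (!is.null(bad)) {
      dropped[[s]] <- paste0("exposure_", bad)
      next
    }
    # outcome: direct match, then proxy, else drop
    orow <- outcome_stats[outcome_stats$snp == s, ]
    provenance <- NULL
    if (nrow(orow) == 0) {
      px <- if (!is.null(ld)) {
        find_proxy(s, outcome_stats, ld, r2_min = proxy_r2,
                   target_bp = ref_row$bp)
      }
      if (is.null(px)) {
        dropped[[s]] <- "missing_from_outcome"
        next
      }
      orow <- outcome_stats[outcome_stats$snp == px$snp, ][1, ]
      if (px$r < 0) {           # orient the proxy's effect allele to the
        orow$beta <- -orow$beta # allele positively correlated with the
        if (!is.na(orow$eaf)) orow$eaf <- 1 - orow$eaf # target's EA
      }
      row$beta_outcome <- orow$beta
      row$se_outcome <- orow$se
      provenance <- paste0("proxy:", px$snp)
    } else {
      al <- align_alleles(ref_row, orow[1, ], palindromic_window)
      if (is.null(al$outcome_row)) {
        dropped[[s]] <- sub("^dropped:", "", al$action)
        next
      }
      row$beta_outcome <- al$outcome_row$beta
      row$se_outcome <- orow$se[1]
      provenance <- al$action
    }
    row$provenance <- provenance
    rows[[s]] <- tibble::as_tibble(row)
  }
  out <- dplyr::bind_rows(rows)
  dropped_tbl <- tibble::tibble(snp = names(dropped) %||% character(0),
                                reason = unname(unlist(dropped)) %||%
                                  character(0))
  structure(out,
            exposures = traits,
            dropped = dropped_tbl,
            retention = if (length(snps)) nrow(out) / length(snps) else NA,
            class = c("mr_harmonised", class(out)))
}

#' @export
print.mr_harmonised <- function(x, ...) {
  cat("<mr_harmonised> ", nrow(x), " SNPs x ",
      length(attr(x, "exposures")), " exposure(s) [",
      paste(attr(x, "exposures"), collapse = ", "), "]; retention ",
      round(100 * attr(x, "retention"), 1), "%\n", sep = "")
  NextMethod()
}

# Extract estimator inputs (B, S, b, s) from an mr_harmonised tibble or any
# data frame with beta_*/se_* and beta_outcome/se_outcome columns.
.mr_inputs <- function(dat, exposures = NULL) {
  if (is.null(exposures)) {
    exposures <- attr(dat, "exposures") %||%
      sub("^beta_", "",
          setdiff(grep("^beta_", names(dat), value = TRUE), "beta_outcome"))
  }
  bcols <- paste0("beta_", exposures); scols <- paste0("se_", exposures)
  missing <- setdiff(c(bcols, scols, "beta_outcome", "se_outcome"),
                     names(dat))
  if (length(missing)) {
    abort(paste("harmonised data lack columns:",
                paste(missing, collapse = ", ")))
  }
  list(B = as.matrix(dat[, bcols, drop = FALSE]),
       S = as.matrix(dat[, scols, drop = FALSE]),
       b = dat$beta_outcome, s = dat$se_outcome,
       snps = dat$snp %||% paste0("snp", seq_len(nrow(dat))),
       exposures = exposures)
}
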