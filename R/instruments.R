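#' Pairwise LD (signed r) between panel SNPs
#'
#' Pearson correlation of dosage columns. The sign is kept (it is needed to
#' orient proxy SNPs); clumping and novelty use r squared.
#'
#' @param panel A `geno_panel`.
#' @param snps Optional subset of SNP ids (default: all).
#' @return A symmetric numeric matrix of class `ld_matrix` with SNP ids as
#'   dimnames and unit diagonal.
#' @export
ld_matrix <- function(panel, snps = NULL) {
  G <- panel$dosages
  if (!is.null(snps)) {
    missing <- setdiff(snps, colnames(G))
    if (length(missing)) {
      abort(paste("SNPs not in panel:", paste(missing, collapse = ", ")))
    }
    G <- G[, snps, drop = FALSE]
  }
  mono <- apply(G, 2, function(g) all(g == g[1]))
  if (any(mono)) {
    abort(paste("correlation undefined for monomorphic SNP(s):",
                paste(colnames(G)[mono], collapse = ", ")))
  }
  r <- cor(G)
  diag(r) <- 1
  class(r) <- c("ld_matrix", class(r))
  r
}

.check_ld_cover <- function(snps, ld) {
  missing <- setdiff(snps, rownames(ld))
  if (length(missing)) {
    abort(paste("SNPs missing from LD matrix:",
                paste(missing, collapse = ", ")))
  }
}

#' Greedy LD clumping
#'
#' Reduces genome-wide significant SNPs to approximately independent index
#' SNPs: sort by p ascending (ties broken by larger `abs(beta)`, then by SNP
#' id), repeatedly retain the best remaining SNP and discard all remaining
#' SNPs on the same chromosome with r-squared at or above the threshold
#' against it. Ordering uses `log10_p`, so underflowed p-values do not
#' produce spurious ties. All same-chromosome pairs are considered (no
#' distance window), which is more conservative than windowed clumping and
#' affordable at desk scale.
#'
#' @param stats Summary-statistics tibble (typically already filtered with
#'   [filter_genome_wide()]).
#' @param ld An `ld_matrix` covering all SNPs in `stats`.
#' @param r2_threshold Discard threshold on r-squared (default 0.001).
#' @return The retained rows of `stats`, in selection order (ascending p),
#'   with attributes `clump_r2` and `members` (named list: index SNP ->
#'   character vector of SNPs it absorbed).
#' @export
ld_clump <- function(stats, ld, r2_threshold = 0.001) {
  if (nrow(stats) == 0) {
    attr(stats, "clump_r2") <- r2_threshold
    attr(stats, "members") <- list()
    return(stats)
  }
  .check_ld_cover(stats$snp, ld)
  lp <- .log10p(stats)
  ord <- order(lp, -abs(stats$beta), stats$snp)
  remaining <- stats$snp[ord]
  chr <- setNames(stats$chr, stats$snp)
  keep <- character(0)
  members <- list()
  while (length(remaining)) {
    idx <- remaining[1]
    keep <- c(keep, idx)
    remaining <- remaining[-1]
    if (length(remaining)) {
      r2 <- ld[idx, remaining]^2
      drop <- r2 >= r2_threshold & chr[remaining] == chr[idx]
      members[[idx]] <- remaining[drop]
      remaining <- remaining[!drop]
    } else {
      members[[idx]] <- character(0)
    }
  }
  out <- stats[match(keep, stats$snp), , drop = FALSE]
  attr(out, "clump_r2") <- r2_threshold
  attr(out, "members") <- members
  out
}

#' Annotate instrument SNPs as novel against a reference catalogue
#'
#' A SNP is flagged novel when every previously reported SNP within 1 Mb on
#' the same chromosome is independent of it (r-squared below `r2_threshold`).
#' A catalogue SNP 2 Mb away is irrelevant however strong its LD; a catalogue
#' SNP inside the window kills novelty only if correlated. Catalogue SNPs
#' absent from the LD matrix are treated as r-squared 0 (reported via a
#' message).
#'
#' @param instruments Clumped summary-statistics tibble.
#' @param catalogue Tibble of previously reported SNPs with columns `snp`,
#'   `chr`, `bp`.
#' @param ld An `ld_matrix` (may omit catalogue SNPs).
#' @param window Distance window in bp (default 1e6).
#' @param r2_threshold Independence threshold (default 0.001).
#' @return `instruments` with a logical `novel` column.
#' @export
annotate_novelty <- function(instruments, catalogue, ld, window = 1e6,
                             r2_threshold = 0.001) {
  unknown <- setdiff(catalogue$snp, rownames(ld))
  if (length(unknown)) {
    inform(paste0(length(unknown), " catalogue SNP(s) absent from the LD ",
                  "matrix; treated as r^2 = 0"))
  }
  novel <- purrr::map_lgl(seq_len(nrow(instruments)), function(i) {
    near <- catalogue[catalogue$chr == instruments$chr[i] &
                        abs(catalogue$bp - instruments$bp[i]) <= window, ]
    if (nrow(near) == 0) return(TRUE)
    known <- intersect(near$snp, rownames(ld))
    if (length(known) == 0) return(TRUE)
    all(ld[instruments$snp[i], known]^2 < r2_threshold)
  })
  dplyr::mutate(instruments, novel = novel)
}

#' Cross-trait overlap of instrument loci
#'
#' Takes the union of per-trait instrument SNPs, re-clumps it to unique loci
#' (ordering by each SNP's best p across traits), and labels each locus with
#' the set of traits for which its index SNP reaches the significance
#' threshold in the full summary statistics — the cells of a Venn diagram of
#' instrument specificity.
#'
#' @param instrument_sets Named list of clumped summary-stat tibbles.
#' @param all_stats Named list of full (unfiltered) summary-stat tibbles, one
#'   per trait, same names.
#' @param ld An `ld_matrix` covering the union.
#' @param p_threshold Trait-association threshold (default 5e-8).
#' @param r2_threshold Re-clumping threshold (default 0.001).
#' @return List with `loci` (tibble: snp, chr, bp, traits as comma-separated
#'   label) and `cells` (tibble: trait_set, n_loci; a partition of the loci).
#' @export
cross_trait_overlap <- function(instrument_sets, all_stats, ld,
                                p_threshold = 5e-8, r2_threshold = 0.001) {
  stopifnot(length(instrument_sets) >= 1,
            all(names(instrument_sets) %in% names(all_stats)))
  ub <- dplyr::bind_rows(instrument_sets)
  ub$.lp <- .log10p(ub)
  union_stats <- ub |>
    dplyr::group_by(.data$snp) |>
    dplyr::slice_min(.data$.lp, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::select(-".lp")
  loci <- ld_clump(union_stats, ld, r2_threshold)
  lt <- log10(p_threshold)
  trait_label <- purrr::map_chr(loci$snp, function(s) {
    hits <- purrr::imap_lgl(all_stats, function(st, nm) {
      row <- st[st$snp == s, , drop = FALSE]
      if (nrow(row) == 0) {
        inform(paste0("SNP ", s, " missing from full stats of ", nm,
                      "; treated as not associated"))
        return(FALSE)
      }
      .log10p(row)[1] < lt
    })
    paste(names(all_stats)[hits], collapse = ",")
  })
  loci_tbl <- tibble::tibble(snp = loci$snp, chr = loci$chr, bp = loci$bp,
                             traits = trait_label)
  cells <- loci_tbl |>
    dplyr::count(.data$traits, name = "n_loci") |>
    dplyr::rename(trait_set = "traits")
  list(loci = loci_tbl, cells = cells)
}
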