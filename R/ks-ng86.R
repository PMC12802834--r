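# Nei-Gojobori (1986) counting of synonymous/nonsynonymous sites and
# differences, with Jukes-Cantor multiple-hit correction.
#
# Conventions (stated because published variants differ):
#   * Sites: each codon position contributes exactly one site, split between
#     synonymous and nonsynonymous in proportion to the single-step mutations
#     at that position that are NOT to a stop codon (S + N = 3 per codon, so
#     S + N = 3 x compared codons).
#   * Differences: codons differing at d positions are resolved by averaging
#     over all d! orderings of the single steps; orderings that pass through
#     a stop codon are excluded. If every ordering is blocked, all orderings
#     are used with the stop treated as an ordinary (nonsynonymous) state.
#   * Codon pairs where either codon contains a non-ACGT character or is a
#     stop are skipped pairwise.

ng86_env <- new.env(parent = emptyenv())

ng86_tables <- function() {
  if (!is.null(ng86_env$aa)) return(invisible(NULL))
  gc <- Biostrings::GENETIC_CODE
  codons <- names(gc)
  aa <- as.character(gc)
  names(aa) <- codons
  frac <- matrix(0, nrow = length(codons), ncol = 3,
                 dimnames = list(codons, NULL))
  for (cod in codons) {
    if (aa[cod] == "*") next
    ch <- strsplit(cod, "")[[1]]
    for (p in 1:3) {
      nsyn <- 0L
      nok <- 0L
      for (b in setdiff(BASES, ch[p])) {
        mut <- ch
        mut[p] <- b
        mc <- paste(mut, collapse = "")
        if (aa[mc] == "*") next
        nok <- nok + 1L
        if (aa[mc] == aa[cod]) nsyn <- nsyn + 1L
      }
      frac[cod, p] <- if (nok > 0L) nsyn / nok else 0
    }
  }
  ng86_env$aa <- aa
  ng86_env$frac <- frac
  ng86_env$syn_sites <- rowSums(frac)
  ng86_env$paths <- new.env(parent = emptyenv())
  invisible(NULL)
}

perms_of <- function(v) {
  if (length(v) == 1L) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in perms_of(v[-i])) out <- c(out, list(c(v[i], rest)))
  }
  out
}

# Average synonymous/nonsynonymous step counts over minimal mutation
# pathways between two sense codons. Memoized.
ng86_path_counts <- function(c1, c2) {
  key <- paste0(c1, c2)
  hit <- ng86_env$paths[[key]]
  if (!is.null(hit)) return(hit)
  aa <- ng86_env$aa
  d1 <- strsplit(c1, "")[[1]]
  d2 <- strsplit(c2, "")[[1]]
  pos <- which(d1 != d2)
  tally <- function(include_stops) {
    sds <- numeric(0)
    nds <- numeric(0)
    for (ord in perms_of(pos)) {
      cur <- d1
      sd_ <- 0
      nd_ <- 0
      ok <- TRUE
      for (p in ord) {
        prev <- paste(cur, collapse = "")
        cur[p] <- d2[p]
        nxt <- paste(cur, collapse = "")
        if (!include_stops && aa[nxt] == "*" && nxt != c2) {
          ok <- FALSE
          break
        }
        if (aa[prev] == aa[nxt]) sd_ <- sd_ + 1 else nd_ <- nd_ + 1
      }
      if (ok) {
        sds <- c(sds, sd_)
        nds <- c(nds, nd_)
      }
    }
    if (length(sds)) c(mean(sds), mean(nds)) else NULL
  }
  res <- tally(FALSE)
  if (is.null(res)) res <- tally(TRUE)
  ng86_env$paths[[key]] <- res
  res
}

#' Synonymous and nonsynonymous distance between two coding sequences (NG86)
#'
#' Counts synonymous/nonsynonymous sites and differences per codon by the
#' Nei-Gojobori (1986) method (multi-difference codons averaged over all
#' minimal mutation pathways, pathways through stop codons excluded) and
#' applies the Jukes-Cantor correction d = -(3/4) ln(1 - (4/3) p). When the
#' correction is inapplicable (p >= 3/4) the corrected distance is `NA` and
#' the raw proportion is retained.
#'
#' @param cds_a,cds_b Codon strings (A/C/G/T), equal length divisible by 3.
#'   Codon pairs containing ambiguity characters or stop codons are skipped.
#' @return Object of class `ks_estimate`: list with S, N (mean site counts),
#'   sd, nd (difference counts), ps, pn (proportions), ks, ka (corrected
#'   distances or NA), codons_used, codons_skipped.
#' @references Nei M & Gojobori T (1986) Mol Biol Evol 3:418-426.
#' @examples
#' ng86_ks("GGGGGG", "GGAGGG")$ks  # (3/4) * log(3)
#' @export
ng86_ks <- function(cds_a, cds_b) {
  if (!is.character(cds_a) || !is.character(cds_b) ||
      length(cds_a) != 1L || length(cds_b) != 1L)
    stop("cds_a and cds_b must be single strings", call. = FALSE)
  a <- toupper(cds_a)
  b <- toupper(cds_b)
  if (nchar(a) != nchar(b))
    stop("sequences must have equal length", call. = FALSE)
  if (nchar(a) == 0L || nchar(a) %% 3L != 0L)
    stop("sequence length must be a positive multiple of 3", call. = FALSE)
  ng86_tables()
  aa <- ng86_env$aa
  n_cod <- nchar(a) %/% 3L
  starts <- 3L * (seq_len(n_cod) - 1L) + 1L
  cod_a <- substring(a, starts, starts + 2L)
  cod_b <- substring(b, starts, starts + 2L)
  valid <- function(cod) {
    !is.na(match(cod, names(aa))) & aa[cod] != "*"
  }
  keep <- valid(cod_a) & valid(cod_b)
  used <- sum(keep)
  S <- 0
  sd_ <- 0
  nd_ <- 0
  if (used > 0L) {
    S <- (sum(ng86_env$syn_sites[cod_a[keep]]) +
          sum(ng86_env$syn_sites[cod_b[keep]])) / 2
    diff_idx <- which(keep & cod_a != cod_b)
    for (i in diff_idx) {
      cnt <- ng86_path_counts(cod_a[i], cod_b[i])
      sd_ <- sd_ + cnt[1]
      nd_ <- nd_ + cnt[2]
    }
  }
  N <- 3 * used - S
  ps <- if (S > 0) sd_ / S else if (sd_ == 0) 0 else NA_real_
  pn <- if (N > 0) nd_ / N else if (nd_ == 0) 0 else NA_real_
  jc <- function(p) {
    if (is.na(p)) return(NA_real_)
    arg <- 1 - (4 / 3) * p
    if (arg <= 0) NA_real_ else -(3 / 4) * log(arg)
  }
  structure(list(S = S, N = N, sd = sd_, nd = nd_, ps = ps, pn = pn,
                 ks = jc(ps), ka = jc(pn),
                 codons_used = used, codons_skipped = n_cod - used),
            class = "ks_estimate")
}

#' @export
print.ks_estimate <- function(x, ...) {
  cat(sprintf(
    "<ks_estimate> S=%.4g N=%.4g sd=%.4g nd=%.4g ps=%.4g pn=%.4g\n",
    x$S, x$N, x$sd, x$nd, x$ps, x$pn))
  cat(sprintf("  ks=%s ka=%s (codons used %d, skipped %d)\n",
              ifelse(is.na(x$ks), "undefined", sprintf("%.6g", x$ks)),
              ifelse(is.na(x$ka), "undefined", sprintf("%.6g", x$ka)),
              x$codons_used, x$codons_skipped))
  invisible(x)
}

#' Ks for many pairs from coding sequences
#'
#' Convenience wrapper applying [ng86_ks()] to a table of gene pairs.
#'
#' @param pairs Tibble with columns gene_a, gene_b.
#' @param cds Named character vector of codon sequences.
#' @return `pairs` with a numeric ks column (NA where undefined or sequences
#'   are missing/incompatible).
#' @export
ng86_ks_pairs <- function(pairs, cds) {
  ks <- rep(NA_real_, nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    sa <- cds[[pairs$gene_a[i]]] %||% NA_character_
    sb <- cds[[pairs$gene_b[i]]] %||% NA_character_
    if (is.na(sa) || is.na(sb) || nchar(sa) != nchar(sb)) next
    est <- tryCatch(ng86_ks(sa, sb), error = function(e) NULL)
    if (!is.null(est)) ks[i] <- est$ks
  }
  pairs$ks <- ks
  pairs
}
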