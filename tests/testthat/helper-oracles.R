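# Independent oracles: deliberately separate, naive codings of the rules the
# package implements, used only to generate expected values.

# ---- exhaustive best-hit / RBH scan -------------------------------------

oracle_best_hits <- function(hits, evalue_max) {
  res <- list()
  for (q in sort(unique(hits$query))) {
    best <- NULL
    for (i in seq_len(nrow(hits))) {
      if (hits$query[i] != q) next
      if (hits$subject[i] == q) next
      if (hits$evalue[i] > evalue_max) next
      cand <- hits[i, ]
      if (is.null(best) ||
          cand$score > best$score ||
          (cand$score == best$score && cand$evalue < best$evalue) ||
          (cand$score == best$score && cand$evalue == best$evalue &&
             cand$subject < best$subject)) {
        best <- cand
      }
    }
    if (!is.null(best)) res[[q]] <- best$subject
  }
  res
}

oracle_rbh_pairs <- function(hits_ab, hits_ba, evalue_max) {
  ba <- oracle_best_hits(hits_ab, evalue_max)
  bb <- oracle_best_hits(hits_ba, evalue_max)
  out <- character(0)
  for (a in names(ba)) {
    b <- ba[[a]]
    if (!is.null(bb[[b]]) && bb[[b]] == a) {
      out <- c(out, paste(sort(c(a, b)), collapse = "|"))
    }
  }
  sort(unique(out))
}

random_hit_table <- function(nq = 8L, ns = 8L, nrows = 30L) {
  q <- sample(sprintf("q%02d", seq_len(nq)), nrows, replace = TRUE)
  s <- sample(sprintf("s%02d", seq_len(ns)), nrows, replace = TRUE)
  tibble::tibble(
    query = q, subject = s,
    # coarse scores so ties actually occur and exercise the tie-break
    score = round(runif(nrows, 10, 60), 0),
    evalue = 10^runif(nrows, -12, -1))
}

# ---- NG86 pathway-enumeration oracle ------------------------------------

oracle_ng86_env <- new.env()

oracle_perms <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (p in oracle_perms(v[-i])) out <- c(out, list(c(v[i], p)))
  out
}

oracle_ng86 <- function(a, b) {
  code <- Biostrings::GENETIC_CODE
  stops <- names(code)[code == "*"]
  split_codons <- function(s) {
    s <- toupper(s)
    substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
  }
  ca <- split_codons(a)
  cb <- split_codons(b)
  ok_codon <- function(cod) {
    cod %in% names(code) && !(cod %in% stops)
  }
  syn_sites_one <- function(cod) {
    s <- 0
    for (p in 1:3) {
      nsyn <- 0
      nok <- 0
      for (base in c("A", "C", "G", "T")) {
        if (base == substr(cod, p, p)) next
        mut <- cod
        substr(mut, p, p) <- base
        if (mut %in% stops) next
        nok <- nok + 1
        if (code[[mut]] == code[[cod]]) nsyn <- nsyn + 1
      }
      if (nok > 0) s <- s + nsyn / nok
    }
    s
  }
  path_counts <- function(c1, c2) {
    key <- paste0(c1, c2)
    memo <- oracle_ng86_env[[key]]
    if (!is.null(memo)) return(memo)
    pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
    run <- function(skip_stops) {
      sds <- c()
      nds <- c()
      for (ord in oracle_perms(pos)) {
        cur <- c1
        sd1 <- 0
        nd1 <- 0
        bad <- FALSE
        for (p in ord) {
          nxt <- cur
          substr(nxt, p, p) <- substr(c2, p, p)
          if (skip_stops && nxt %in% stops && nxt != c2) {
            bad <- TRUE
            break
          }
          if (code[[cur]] == code[[nxt]]) sd1 <- sd1 + 1 else nd1 <- nd1 + 1
          cur <- nxt
        }
        if (!bad) {
          sds <- c(sds, sd1)
          nds <- c(nds, nd1)
        }
      }
      if (length(sds)) c(mean(sds), mean(nds)) else NULL
    }
    res <- run(TRUE)
    if (is.null(res)) res <- run(FALSE)
    oracle_ng86_env[[key]] <- res
    res
  }
  S <- 0
  sd_ <- 0
  nd_ <- 0
  used <- 0
  for (i in seq_along(ca)) {
    if (!ok_codon(ca[i]) || !ok_codon(cb[i])) next
    used <- used + 1
    S <- S + (syn_sites_one(ca[i]) + syn_sites_one(cb[i])) / 2
    if (ca[i] != cb[i]) {
      pc <- path_counts(ca[i], cb[i])
      sd_ <- sd_ + pc[1]
      nd_ <- nd_ + pc[2]
    }
  }
  N <- 3 * used - S
  ps <- if (S > 0) sd_ / S else if (sd_ == 0) 0 else NA_real_
  ks <- if (is.na(ps) || 1 - 4 * ps / 3 <= 0) NA_real_
        else -0.75 * log(1 - 4 * ps / 3)
  list(S = S, N = N, sd = sd_, nd = nd_, ps = ps, ks = ks)
}

random_codon_pair <- function(n_codons = 30L, n_mut = 6L, junk_prob = 0.02) {
  code <- Biostrings::GENETIC_CODE
  sense <- names(code)[code != "*"]
  a <- sample(sense, n_codons, replace = TRUE)
  b <- a
  for (k in seq_len(n_mut)) {
    i <- sample.int(n_codons, 1)
    p <- sample.int(3L, 1)
    substr(b[i], p, p) <- sample(c("A", "C", "G", "T"), 1)
  }
  a <- paste(a, collapse = "")
  b <- paste(b, collapse = "")
  if (runif(1) < junk_prob) {
    i <- sample.int(nchar(a), 1)
    substr(a, i, i) <- "N"
  }
  list(a = a, b = b)
}

# ---- segment-calling scan oracle ----------------------------------------

# Left-to-right scan per AC, then the same published overlap rule (more
# assigned genes win; ties by start, then AC), recoded independently.
oracle_segments <- function(labels, min_run, max_gap) {
  labels <- as.character(labels)
  n <- length(labels)
  cand <- data.frame(ac = character(0), start = integer(0), end = integer(0),
                     length = integer(0), stringsAsFactors = FALSE)
  for (ac in sort(unique(labels[!is.na(labels)]))) {
    start <- NA_integer_
    last <- NA_integer_
    cnt <- 0L
    gap <- 0L
    flush <- function() {
      if (!is.na(start) && cnt >= min_run) {
        cand <<- rbind(cand, data.frame(ac = ac, start = start - 1L,
                                        end = last, length = cnt,
                                        stringsAsFactors = FALSE))
      }
    }
    for (i in seq_len(n)) {
      lab <- labels[i]
      if (!is.na(lab) && lab == ac) {
        if (is.na(start)) start <- i
        last <- i
        cnt <- cnt + 1L
        gap <- 0L
      } else if (!is.na(start)) {
        gap <- gap + 1L
        if (gap > max_gap) {
          flush()
          start <- NA_integer_
          cnt <- 0L
          gap <- 0L
        }
      }
    }
    flush()
  }
  if (nrow(cand) == 0L) return(cand)
  cand <- cand[order(-cand$length, cand$start, cand$ac), , drop = FALSE]
  chosen <- cand[0, ]
  for (i in seq_len(nrow(cand))) {
    clash <- FALSE
    if (nrow(chosen) > 0) {
      for (j in seq_len(nrow(chosen))) {
        if (cand$start[i] < chosen$end[j] && chosen$start[j] < cand$end[i])
          clash <- TRUE
      }
    }
    if (!clash) chosen <- rbind(chosen, cand[i, ])
  }
  chosen <- chosen[order(chosen$start), , drop = FALSE]
  rownames(chosen) <- NULL
  chosen
}

random_label_string <- function(len, p_na = 0.3, acs = c("A", "B")) {
  x <- sample(c(acs, NA), len, replace = TRUE,
              prob = c(rep((1 - p_na) / length(acs), length(acs)), p_na))
  as.character(x)
}
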