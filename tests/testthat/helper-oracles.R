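# Independent brute-force oracles, deliberately written without reusing any
# package internals: plain loops and base R only.

# ---- class-code rule checker ---------------------------------------------
bf_introns <- function(t) {
  ex <- t$exons
  if (nrow(ex) < 2) return(matrix(numeric(0), ncol = 2))
  cbind(ex$end[-nrow(ex)] + 1, ex$start[-1] - 1)
}

bf_overlap <- function(s1, e1, s2, e2) s1 <= e2 && s2 <= e1

bf_class_code <- function(q, refs) {
  qs <- q$exons$start[1]
  qe <- q$exons$end[nrow(q$exons)]
  cand <- Filter(function(r) {
    r$chrom == q$chrom &&
      bf_overlap(qs, qe, r$exons$start[1], r$exons$end[nrow(r$exons)])
  }, refs)
  if (!length(cand)) return("u")
  qi <- bf_introns(q)
  for (r in cand) {
    if (r$strand != q$strand) next
    ri <- bf_introns(r)
    if (nrow(qi) == nrow(ri) &&
        (nrow(qi) == 0 || all(qi == ri))) {
      if (nrow(qi) > 0) return("=")
      # single-exon vs single-exon: need exon overlap
      hit <- FALSE
      for (a in seq_len(nrow(q$exons)))
        for (b in seq_len(nrow(r$exons)))
          if (bf_overlap(q$exons$start[a], q$exons$end[a],
                         r$exons$start[b], r$exons$end[b])) hit <- TRUE
      if (hit) return("=")
    }
  }
  if (nrow(qi) > 0) {
    for (r in cand) {
      if (r$strand != q$strand) next
      ri <- bf_introns(r)
      if (!nrow(ri)) next
      for (a in seq_len(nrow(qi)))
        for (b in seq_len(nrow(ri)))
          if (qi[a, 1] == ri[b, 1] && qi[a, 2] == ri[b, 2]) return("j")
    }
  }
  for (r in cand) {
    if (r$strand == q$strand) next
    for (a in seq_len(nrow(q$exons)))
      for (b in seq_len(nrow(r$exons)))
        if (bf_overlap(q$exons$start[a], q$exons$end[a],
                       r$exons$start[b], r$exons$end[b])) return("x")
  }
  for (r in cand) {
    if (r$strand != q$strand) next
    ri <- bf_introns(r)
    if (!nrow(ri)) next
    for (b in seq_len(nrow(ri)))
      if (ri[b, 1] <= qs && qe <= ri[b, 2]) return("i")
  }
  "other"
}

# random transcript generator used to fuzz the class-code rules
random_transcript <- function(id, chrom, strand, lo, hi, max_exons = 4) {
  n_ex <- sample(max_exons, 1)
  # draw exon/intron widths then place at a random offset
  widths <- sample(30:200, n_ex, replace = TRUE)
  gaps <- if (n_ex > 1) sample(20:300, n_ex - 1, replace = TRUE) else integer(0)
  total <- sum(widths) + sum(gaps)
  start <- sample(lo:max(lo, hi - total), 1)
  s <- integer(n_ex); e <- integer(n_ex)
  pos <- start
  for (k in seq_len(n_ex)) {
    s[k] <- pos; e[k] <- pos + widths[k] - 1
    pos <- e[k] + 1 + if (k < n_ex) gaps[k] else 0
  }
  transcript_model(id, paste0("g_", id), chrom, strand, s, e)
}

# ---- open-reading-frame enumeration --------------------------------------
bf_longest_orf <- function(seq) {
  s <- toupper(seq)
  n <- nchar(s)
  best <- NA_integer_
  stops <- c("TAA", "TAG", "TGA")
  for (i in seq_len(max(n - 5, 0))) {
    if (substr(s, i, i + 2) != "ATG") next
    j <- i + 3
    while (j + 2 <= n) {
      if (substr(s, j, j + 2) %in% stops) {
        len <- (j - i) / 3
        if (is.na(best) || len > best) best <- len
        break
      }
      j <- j + 3
    }
  }
  as.integer(best)
}

# ---- Fisher combination ---------------------------------------------------
bf_fisher <- function(p) {
  stats::pchisq(-2 * sum(log(p)), df = 2 * length(p), lower.tail = FALSE)
}

# ---- hypergeometric upper tail by exhaustive draw enumeration -------------
bf_hyper_upper <- function(N, K, n, k) {
  draws <- utils::combn(N, n)
  in_set <- function(d) sum(d <= K)  # items 1..K form the category
  hits <- apply(draws, 2, in_set)
  mean(hits >= k)
}

# ---- Benjamini-Hochberg step-up ------------------------------------------
bf_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

# ---- small paired design sheet -------------------------------------------
make_sheet <- function(dams_per_parity = c(2, 2, 2, 2)) {
  dams <- sprintf("D%02d", seq_len(sum(dams_per_parity)))
  parity <- rep(1:4, times = dams_per_parity)
  data.frame(
    sample_id = c(paste0(dams, "_C"), paste0(dams, "_M")),
    dam_id = rep(dams, 2),
    milk_type = rep(c("colostrum", "milk"), each = length(dams)),
    parity = rep(parity, 2))
}
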