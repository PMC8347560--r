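# Independent brute-force oracle for the canonical G4 scanner.
#
# Enumerates every (start, tract lengths t1..t4, loop lengths l1..l3) tuple,
# keeps the tuples whose characters satisfy the motif grammar with maximal
# tracts (flanking characters and loop edge characters are non-G), then
# applies the leftmost non-overlapping selection with nearest-tract
# (lexicographically minimal loop vector) tie-break. Implemented as plain
# nested enumeration, independent of the run-graph search in scan_g4().
brute_scan <- function(sequence) {
  chars <- strsplit(toupper(gsub("U", "T", sequence)), "")[[1]]
  n <- length(chars)
  g <- chars == "G"
  tuples <- list()
  for (s in 0:(n - 15)) {
    if (s > 0 && g[s]) next                      # tract 1 must be maximal
    for (t1 in 3:(n - s - 12)) {
      if (s + t1 > n || !all(g[(s + 1):(s + t1)])) break
      p1 <- s + t1
      if (p1 < n && g[p1 + 1]) next              # loop 1 starts non-G
      for (l1 in 1:7) {
        p2 <- p1 + l1                            # start of tract 2
        if (p2 + 3 > n || g[p2]) next            # loop 1 ends non-G
        for (t2 in 3:(n - p2)) {
          if (p2 + t2 > n || !all(g[(p2 + 1):(p2 + t2)])) break
          q2 <- p2 + t2
          if (q2 < n && g[q2 + 1]) next
          for (l2 in 1:7) {
            p3 <- q2 + l2
            if (p3 + 3 > n || g[p3]) next
            for (t3 in 3:(n - p3)) {
              if (p3 + t3 > n || !all(g[(p3 + 1):(p3 + t3)])) break
              q3 <- p3 + t3
              if (q3 < n && g[q3 + 1]) next
              for (l3 in 1:7) {
                p4 <- q3 + l3
                if (p4 + 3 > n || g[p4]) next
                for (t4 in 3:(n - p4)) {
                  if (p4 + t4 > n || !all(g[(p4 + 1):(p4 + t4)])) break
                  e <- p4 + t4
                  if (e < n && g[e + 1]) next    # tract 4 maximal
                  tuples[[length(tuples) + 1]] <-
                    c(s, e, t1, t2, t3, t4, l1, l2, l3)
                }
              }
            }
          }
        }
      }
    }
  }
  if (length(tuples) == 0)
    return(data.frame(start = integer(), end = integer(),
                      quartets = integer(), loop1 = integer(),
                      loop2 = integer(), loop3 = integer()))
  tb <- do.call(rbind, tuples)
  colnames(tb) <- c("start", "end", "t1", "t2", "t3", "t4",
                    "l1", "l2", "l3")
  tb <- as.data.frame(tb)
  # leftmost, non-overlapping; nearest-tract tie-break = lexicographically
  # minimal (l1, l2, l3) among tuples sharing the minimal start
  out <- list()
  limit <- 0
  repeat {
    cand <- tb[tb$start >= limit, , drop = FALSE]
    if (nrow(cand) == 0) break
    cand <- cand[cand$start == min(cand$start), , drop = FALSE]
    cand <- cand[order(cand$l1, cand$l2, cand$l3), , drop = FALSE]
    pick <- cand[1, ]
    out[[length(out) + 1]] <- pick
    limit <- pick$end
  }
  res <- do.call(rbind, out)
  data.frame(start = res$start, end = res$end,
             quartets = pmin(pmin(res$t1, res$t2), pmin(res$t3, res$t4)),
             loop1 = res$l1, loop2 = res$l2, loop3 = res$l3)
}

motif_keys <- function(x) paste(x$transcript_id, x$start, x$end, sep = ":")

# Random test strings: G-rich so motifs actually occur.
random_g_string <- function(len, p_g = 0.4) {
  paste(sample(c("G", "A", "C", "T"), len, replace = TRUE,
               prob = c(p_g, rep((1 - p_g) / 3, 3))), collapse = "")
}
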