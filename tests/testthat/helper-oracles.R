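# Independent brute-force oracles and fixture builders used across tests.
# These deliberately re-implement the documented event definitions with
# plain loops, sharing no code with the package internals.

make_tx <- function(tid, starts, ends, strand = "+", gene = "g1",
                    chrom = "chr1") {
  tibble::tibble(transcript_id = tid, gene_id = gene, chrom = chrom,
                 start = as.integer(starts), end = as.integer(ends),
                 strand = strand)
}

# random valid exon chain within [0, region)
rand_chain <- function(tid, region = 5000L, strand = "+", gene = "g1") {
  n_ex <- sample(1:6, 1)
  points <- sort(sample(seq(0L, region - 1L), 2L * n_ex))
  # enforce gaps >= 1 by construction: points are distinct and ordered
  make_tx(tid, points[seq(1, 2 * n_ex, 2)], points[seq(2, 2 * n_ex, 2)],
          strand, gene)
}

# perturb a chain with one structural edit, keeping it valid
perturb_chain <- function(ex, tid) {
  n <- nrow(ex)
  ops <- c("merge", "drop", "shift")
  op <- sample(ops, 1)
  if (op == "merge" && n >= 2) {
    i <- sample(n - 1, 1)
    ex2 <- ex[-i, ]
    ex2$start[i] <- ex$start[i]
  } else if (op == "drop" && n >= 3) {
    i <- sample(2:(n - 1), 1)
    ex2 <- ex[-i, ]
  } else if (n >= 2) {
    i <- sample(n - 1, 1)
    gap <- ex$start[i + 1] - ex$end[i]
    exlen <- ex$end[i] - ex$start[i]
    d <- sample(-(exlen - 1):(gap - 1), 1)
    ex2 <- ex
    ex2$end[i] <- ex$end[i] + d
  } else {
    ex2 <- ex
    ex2$end[1] <- ex$end[1] + sample(1:50, 1)
  }
  ex2$transcript_id <- tid
  ex2
}

rand_pair <- function(region = 5000L) {
  strand <- sample(c("+", "-"), 1)
  a <- rand_chain("tA", region, strand)
  if (stats::runif(1) < 0.6) {
    b <- a
    for (k in seq_len(sample(1:3, 1))) b <- perturb_chain(b, "tB")
    b$transcript_id <- "tB"
  } else {
    b <- rand_chain("tB", region, strand)
  }
  list(a = a, b = b)
}

okey <- function(s, e) sprintf("%d-%d", s, e)

oracle_introns <- function(ex) {
  ex <- ex[order(ex$start), ]
  if (nrow(ex) < 2) {
    return(data.frame(s = integer(0), e = integer(0)))
  }
  data.frame(s = ex$end[-nrow(ex)], e = ex$start[-1])
}

# brute-force enumerator over containment and shared-boundary relations,
# following the documented five-type definitions
oracle_classify <- function(a, b) {
  a <- a[order(a$start), ]; b <- b[order(b$start), ]
  strand <- a$strand[1]
  rows <- list()
  add <- function(type, as, ae, jx, on, off) {
    rows[[length(rows) + 1]] <<- data.frame(
      event_type = type, affected_start = as, affected_end = ae,
      junctions = jx, on_isoforms = on, off_isoforms = off,
      stringsAsFactors = FALSE)
  }
  # intron retention
  for (xy in list(list(a, b), list(b, a))) {
    x <- xy[[1]]; y <- xy[[2]]
    ix <- oracle_introns(x)
    for (i in seq_len(nrow(ix))) {
      for (j in seq_len(nrow(y))) {
        if (y$start[j] <= ix$s[i] && ix$e[i] <= y$end[j]) {
          add("IntronR", ix$s[i], ix$e[i], okey(ix$s[i], ix$e[i]),
              y$transcript_id[1], x$transcript_id[1])
        }
      }
    }
  }
  # exon skipping
  for (xy in list(list(a, b), list(b, a))) {
    x <- xy[[1]]; y <- xy[[2]]
    iy <- oracle_introns(y)
    if (nrow(x) < 3) next
    for (k in 2:(nrow(x) - 1)) {
      span_ok <- FALSE
      for (m in seq_len(nrow(iy))) {
        if (iy$s[m] == x$end[k - 1] && iy$e[m] == x$start[k + 1]) span_ok <- TRUE
      }
      ov <- FALSE
      for (j in seq_len(nrow(y))) {
        if (x$start[k] < y$end[j] && y$start[j] < x$end[k]) ov <- TRUE
      }
      if (span_ok && !ov) {
        add("ExonS", x$start[k], x$end[k],
            paste(okey(x$end[k - 1], x$start[k]),
                  okey(x$end[k], x$start[k + 1]), sep = ";"),
            x$transcript_id[1], y$transcript_id[1])
      }
    }
  }
  # alternative donor/acceptor
  ia <- oracle_introns(a); ib <- oracle_introns(b)
  for (i in seq_len(nrow(ia))) for (j in seq_len(nrow(ib))) {
    same_s <- ia$s[i] == ib$s[j]; same_e <- ia$e[i] == ib$e[j]
    if (same_s == same_e) next
    if (same_s) {
      type <- if (strand == "+") "AltA" else "AltD"
      lo <- min(ia$e[i], ib$e[j]); hi <- max(ia$e[i], ib$e[j])
      short_tx <- if (ia$e[i] < ib$e[j]) a else b
      long_tx <- if (ia$e[i] < ib$e[j]) b else a
    } else {
      type <- if (strand == "+") "AltD" else "AltA"
      lo <- min(ia$s[i], ib$s[j]); hi <- max(ia$s[i], ib$s[j])
      short_tx <- if (ia$s[i] > ib$s[j]) a else b
      long_tx <- if (ia$s[i] > ib$s[j]) b else a
    }
    inside <- FALSE
    for (k in seq_len(nrow(short_tx))) {
      if (short_tx$start[k] <= lo && hi <= short_tx$end[k]) inside <- TRUE
    }
    if (!inside) next
    jx <- paste(sort(c(okey(ia$s[i], ia$e[i]), okey(ib$s[j], ib$e[j]))),
                collapse = ";")
    add(type, lo, hi, jx, short_tx$transcript_id[1], long_tx$transcript_id[1])
  }
  # alternate terminal exon
  if (nrow(a) >= 2 && nrow(b) >= 2) {
    for (side in c("5p", "3p")) {
      genomic_first <- (side == "5p") == (strand == "+")
      ta <- if (genomic_first) a[1, ] else a[nrow(a), ]
      tb <- if (genomic_first) b[1, ] else b[nrow(b), ]
      ja <- if (genomic_first) ia[1, ] else ia[nrow(ia), ]
      jb <- if (genomic_first) ib[1, ] else ib[nrow(ib), ]
      if (ja$s == jb$s && ja$e == jb$e) next
      a_free <- TRUE; b_free <- TRUE
      for (j in seq_len(nrow(b))) {
        if (ta$start < b$end[j] && b$start[j] < ta$end) a_free <- FALSE
      }
      for (j in seq_len(nrow(a))) {
        if (tb$start < a$end[j] && a$start[j] < tb$end) b_free <- FALSE
      }
      if (!a_free && !b_free) next
      cand <- rbind(if (a_free) ta else NULL, if (b_free) tb else NULL)
      pick <- if (genomic_first) which.min(cand$start) else which.max(cand$end)
      ex <- cand[pick, ]
      other <- if (ex$transcript_id == a$transcript_id[1]) b else a
      add("AltTE", ex$start, ex$end,
          paste(sort(c(okey(ja$s, ja$e), okey(jb$s, jb$e))), collapse = ";"),
          ex$transcript_id, other$transcript_id[1])
    }
  }
  if (length(rows) == 0) {
    return(data.frame(event_type = character(), affected_start = integer(),
                      affected_end = integer(), junctions = character(),
                      on_isoforms = character(), off_isoforms = character(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- out[!duplicated(out[, c("event_type", "affected_start",
                                 "affected_end", "junctions")]), ]
  out[order(out$event_type, out$affected_start, out$affected_end,
            out$junctions), ]
}

# canonical form for comparing event tables
event_canon <- function(ev) {
  ev <- as.data.frame(ev)[, c("event_type", "affected_start", "affected_end",
                              "junctions", "on_isoforms", "off_isoforms")]
  ev <- ev[order(ev$event_type, ev$affected_start, ev$affected_end,
                 ev$junctions), ]
  rownames(ev) <- NULL
  ev
}

# Lance-Williams recursion for Ward linkage on squared Euclidean
# distances (heights on the original scale), independent of stats::hclust
oracle_ward_heights <- function(x) {
  n <- nrow(x)
  d2 <- as.matrix(dist(x))^2
  sizes <- rep(1, n)
  active <- seq_len(n)
  heights <- numeric(0)
  while (length(active) > 1) {
    best <- c(NA, NA); bestv <- Inf
    for (i in seq_along(active)) for (j in seq_along(active)) {
      if (i < j) {
        v <- d2[active[i], active[j]]
        if (v < bestv) { bestv <- v; best <- c(active[i], active[j]) }
      }
    }
    i <- best[1]; j <- best[2]
    heights <- c(heights, sqrt(bestv))
    for (k in setdiff(active, c(i, j))) {
      ni <- sizes[i]; nj <- sizes[j]; nk <- sizes[k]
      d2[i, k] <- d2[k, i] <-
        ((ni + nk) * d2[i, k] + (nj + nk) * d2[j, k] - nk * d2[i, j]) /
        (ni + nj + nk)
    }
    sizes[i] <- sizes[i] + sizes[j]
    active <- setdiff(active, j)
  }
  heights
}
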