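## Independent oracles the implementation is checked against. These are
## deliberately naive (enumeration / brute force) and share no code with
## the package internals.

## O(n^2) interval-overlap oracle: closed 1-based intervals overlap iff
## a.start <= b.end and b.start <= a.end on the same chromosome.
oracle_overlaps <- function(a, b) {
  out <- list()
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      if (a$chrom[i] == b$chrom[j] &&
          a$start[i] <= b$end[j] && b$start[j] <= a$end[i])
        out[[length(out) + 1L]] <- c(i, j)
    }
  }
  if (!length(out)) return(data.frame(a = integer(0), b = integer(0)))
  m <- do.call(rbind, out)
  out <- data.frame(a = m[, 1], b = m[, 2])
  out[order(out$a, out$b), , drop = FALSE]
}

## Brute-force six-frame ORF scanner built on seqinr translation.
## Definition: within each frame of each scanned strand, an ORF runs from
## the first ATG after the previous terminator (stop codon, untranslatable
## codon, or frame start) to the next terminator; reported if its peptide
## has at least min_aa residues; partial when not ended by a stop codon.
oracle_orfs <- function(seq, min_aa = 100, both_strands = TRUE) {
  scan1 <- function(s, label) {
    L <- nchar(s)
    rows <- list()
    for (fr in 0:2) {
      aa <- seqinr::translate(seqinr::s2c(s), frame = fr)
      if (!length(aa)) next
      term <- which(aa == "*" | aa == "X")
      seg_start <- c(1L, term + 1L)
      seg_end <- c(term - 1L, length(aa))
      for (k in seq_along(seg_start)) {
        lo <- seg_start[k]; hi <- seg_end[k]
        if (lo > hi) next
        ms <- which(aa[lo:hi] == "M")
        if (!length(ms)) next
        m0 <- lo + ms[1] - 1L
        pep <- paste(aa[m0:hi], collapse = "")
        if (nchar(pep) < min_aa) next
        stopped <- (hi + 1L) <= length(aa) && aa[hi + 1L] == "*"
        nt_start <- fr + 3L * (m0 - 1L) + 1L
        nt_end <- fr + 3L * (if (stopped) hi + 1L else hi)
        if (label == "antisense") {
          tmp <- L - nt_end + 1L
          nt_end <- L - nt_start + 1L
          nt_start <- tmp
        }
        rows[[length(rows) + 1L]] <- data.frame(
          strand = label, frame = fr, start = nt_start, end = nt_end,
          peptide = pep, length_aa = nchar(pep), partial = !stopped,
          stringsAsFactors = FALSE)
      }
    }
    rows
  }
  rc <- function(s) {
    paste(rev(seqinr::comp(seqinr::s2c(s), forceToLower = FALSE,
                           ambiguous = TRUE)), collapse = "")
  }
  rows <- scan1(toupper(seq), "sense")
  if (both_strands) rows <- c(rows, scan1(rc(toupper(seq)), "antisense"))
  if (!length(rows))
    return(data.frame(strand = character(0), frame = integer(0),
                      start = integer(0), end = integer(0),
                      peptide = character(0), length_aa = integer(0),
                      partial = logical(0)))
  out <- do.call(rbind, rows)
  out[order(out$strand, out$frame, out$start), , drop = FALSE]
}

## Naive average-linkage agglomeration from a dissimilarity matrix.
## Returns the cophenetic matrix and the canonical leaf order (children
## of every merge ordered by their smallest leaf index).
oracle_average_linkage <- function(d) {
  n <- nrow(d)
  coph <- matrix(0, n, n)
  members <- as.list(seq_len(n))
  work <- d
  diag(work) <- Inf
  active <- seq_len(n)
  while (length(active) > 1L) {
    sub <- work[active, active, drop = FALSE]
    ix <- which(sub == min(sub), arr.ind = TRUE)[1, ]
    i <- active[min(ix)]; j <- active[max(ix)]
    h <- work[i, j]
    for (x in members[[i]]) for (y in members[[j]]) {
      coph[x, y] <- h; coph[y, x] <- h
    }
    ni <- length(members[[i]]); nj <- length(members[[j]])
    for (k in setdiff(active, c(i, j)))
      work[i, k] <- work[k, i] <- (ni * work[i, k] + nj * work[j, k]) /
        (ni + nj)
    ## canonical child order: block with the smallest leaf first
    members[[i]] <- if (min(members[[i]]) <= min(members[[j]]))
      c(members[[i]], members[[j]]) else c(members[[j]], members[[i]])
    active <- setdiff(active, j)
  }
  list(cophenetic = coph, order = members[[active]])
}

## Canonical leaf order of an hclust tree (children of every merge
## ordered by smallest leaf index), so trees can be compared without
## depending on hclust's internal row-ordering conventions.
canonical_hclust_order <- function(h) {
  rec <- function(k) {
    if (k < 0) return(-k)
    l <- rec(h$merge[k, 1]); r <- rec(h$merge[k, 2])
    if (min(l) <= min(r)) c(l, r) else c(r, l)
  }
  rec(nrow(h$merge))
}
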