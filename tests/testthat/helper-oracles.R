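# Independent brute-force oracles used across the suite. These stay
# deliberately naive (site-by-site loops, full enumeration) so that they
# are not the implementation under test.

# coverage filter: returns list(keep = logical per site,
# zeroed = logical matrix) by direct rule application
bf_filter <- function(cov, group, min_cov = 6, min_frac = 0.5) {
  keep <- logical(nrow(cov))
  for (i in seq_len(nrow(cov))) {
    fc <- mean(cov[i, group == "case"] >= min_cov)
    fo <- mean(cov[i, group == "control"] >= min_cov)
    keep[i] <- fc >= min_frac && fo >= min_frac
  }
  list(keep = keep, zeroed = cov < min_cov)
}

# BH from the definition: padj_i = min_{j >= rank(i)} m * p_(j) / j
bf_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj_sorted <- vapply(seq_len(m), function(i) {
    min(pmin(1, m * ps[i:m] / (i:m)))
  }, numeric(1))
  out <- numeric(m)
  out[o] <- adj_sorted
  out
}

# interval gap by case enumeration
bf_distance <- function(ca, sa, ea, cb, sb, eb) {
  if (ca != cb) return(NA_integer_)
  if (sa < eb && sb < ea) return(0L)          # overlap
  if (ea <= sb) return(sb - ea)               # a left of b
  sa - eb
}

# all-pairs window scan
bf_pairs <- function(left, right, window) {
  out <- list()
  for (i in seq_len(nrow(left))) {
    for (j in seq_len(nrow(right))) {
      d <- bf_distance(left$chrom[i], left$start[i], left$end[i],
                       right$chrom[j], right$start[j], right$end[j])
      if (!is.na(d) && d <= window) {
        out[[length(out) + 1L]] <- data.frame(
          left_id = left$id[i], right_id = right$id[j], distance_bp = d)
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(left_id = character(), right_id = character(),
                      distance_bp = integer()))
  }
  do.call(rbind, out)
}

# Wilcoxon rank-sum U for x (vs y), counting pairs
bf_U <- function(x, y) {
  u <- 0
  for (xi in x) for (yj in y) {
    u <- u + (xi > yj) + 0.5 * (xi == yj)
  }
  u
}

# per-region per-sample mean beta by explicit loops
bf_region_beta <- function(sites, meth, cov, regions) {
  out <- matrix(NA_real_, nrow(regions), ncol(meth),
                dimnames = list(regions$dmr_id, colnames(meth)))
  for (r in seq_len(nrow(regions))) {
    for (s in seq_len(ncol(meth))) {
      vals <- c()
      for (i in seq_len(nrow(sites))) {
        if (sites$chrom[i] == regions$chrom[r] &&
            sites$pos[i] - 1 >= regions$start[r] &&
            sites$pos[i] - 1 < regions$end[r] && cov[i, s] > 0) {
          vals <- c(vals, meth[i, s] / cov[i, s])
        }
      }
      if (length(vals)) out[r, s] <- mean(vals)
    }
  }
  out
}

# construct a cpg_matrix directly from matrices
make_cpg <- function(chrom, pos, meth, cov, group) {
  structure(list(sites = data.table::data.table(chrom = chrom, pos = pos),
                 meth = meth, cov = cov, group = group),
            class = "cpg_matrix")
}
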