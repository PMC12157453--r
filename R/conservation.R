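.AA <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# Accepts an AAStringSet / character vector of equal-length aligned
# sequences and returns a character matrix (rows = sequences).
.alignment_matrix <- function(alignment) {
  if (inherits(alignment, "AAStringSet") || inherits(alignment, "XStringSet")) {
    seqs <- as.character(alignment)
  } else {
    seqs <- alignment
  }
  if (is.null(names(seqs))) stop("alignment sequences must be named")
  if (length(unique(nchar(seqs))) != 1) {
    stop("aligned sequences must all have equal length")
  }
  m <- do.call(rbind, strsplit(toupper(seqs), ""))
  rownames(m) <- names(seqs)
  m
}

#' Split an alignment into two groups
#'
#' Separates a multiple sequence alignment into two sub-alignments by group
#' membership — e.g. isoforms that traffic to the cell surface versus
#' those that do not. Every sequence must be mapped to exactly one group.
#'
#' @param alignment Aligned sequences: a named character vector or a
#'   `Biostrings::AAStringSet` (see [read_alignment()]).
#' @param group_map Either a `data.frame` with columns `sequence_id` and
#'   `group` (exactly two distinct groups) or a named character vector
#'   `c(sequence_id = group)`.
#' @param region Optional integer pair `c(start, end)` of 1-based,
#'   inclusive alignment columns to restrict to (e.g. the EC6 interval).
#' @return Object of class `grouped_alignment`: character matrices `a` and
#'   `b`, `group_names` (a first), `region`, and `offset` (first column of
#'   the region in original alignment coordinates).
#' @export
split_alignment <- function(alignment, group_map, region = NULL) {
  m <- .alignment_matrix(alignment)
  if (is.data.frame(group_map)) {
    gm <- stats::setNames(as.character(group_map$group),
                          as.character(group_map$sequence_id))
  } else {
    gm <- group_map
  }
  missing_ids <- setdiff(rownames(m), names(gm))
  if (length(missing_ids) > 0) {
    stop("sequences missing from group map: ",
         paste(missing_ids, collapse = ", "))
  }
  groups <- sort(unique(gm[rownames(m)]))
  if (length(groups) != 2) {
    stop("group map must define exactly two groups, got: ",
         paste(groups, collapse = ", "))
  }
  offset <- 1L
  if (!is.null(region)) {
    stopifnot(length(region) == 2, region[1] >= 1, region[2] <= ncol(m),
              region[1] <= region[2])
    m <- m[, region[1]:region[2], drop = FALSE]
    offset <- as.integer(region[1])
  }
  structure(
    list(a = m[gm[rownames(m)] == groups[1], , drop = FALSE],
         b = m[gm[rownames(m)] == groups[2], , drop = FALSE],
         group_names = groups, region = region, offset = offset),
    class = "grouped_alignment")
}

#' @export
print.grouped_alignment <- function(x, ...) {
  cat(sprintf("Grouped alignment: %d columns; '%s' n=%d, '%s' n=%d\n",
              ncol(x$a), x$group_names[1], nrow(x$a),
              x$group_names[2], nrow(x$b)))
  invisible(x)
}

#' Amino-acid frequencies of one alignment column
#'
#' Counts residues over the 20-letter amino-acid alphabet, excluding gaps
#' (and any non-standard symbol, treated like a gap), and normalizes with a
#' Laplace-style pseudocount: `(count_i + eps) / (n_eff + 20 eps)` where
#' `n_eff` is the number of counted residues. The pseudocount keeps every
#' entry strictly positive so Kullback-Leibler divergences stay finite at
#' fully disjoint columns.
#'
#' @param sub_alignment Character matrix (rows = sequences) or character
#'   vector of single residues for one column.
#' @param column Column index when a matrix is given.
#' @param pseudocount Non-negative smoothing constant `eps`.
#' @return Named numeric vector over the 20 amino acids summing to 1, or
#'   all-`NA` for an all-gap column.
#' @export
column_frequencies <- function(sub_alignment, column = NULL,
                               pseudocount = 0) {
  chars <- if (is.matrix(sub_alignment)) {
    stopifnot(!is.null(column), column >= 1, column <= ncol(sub_alignment))
    sub_alignment[, column]
  } else {
    sub_alignment
  }
  counts <- vapply(.AA, function(a) sum(chars == a), 0)
  n_eff <- sum(counts)
  if (n_eff == 0) return(stats::setNames(rep(NA_real_, 20), .AA))
  (counts + pseudocount) / (n_eff + 20 * pseudocount)
}

#' Kullback-Leibler divergence between two distributions
#'
#' `KL(p || q) = sum_i p_i ln(p_i / q_i)` in nats. Non-negative, zero iff
#' `p == q`, and asymmetric in its arguments. Requires strictly positive
#' `q` (use a pseudocount upstream); `p` entries of exactly 0 contribute 0.
#'
#' @param p,q Probability vectors of equal length summing to 1.
#' @return Non-negative scalar (nats).
#' @export
kl_divergence <- function(p, q) {
  if (length(p) != length(q)) stop("p and q must have equal length")
  if (abs(sum(p) - 1) > 1e-6 || abs(sum(q) - 1) > 1e-6) {
    stop("p and q must each sum to 1")
  }
  if (any(q <= 0 & p > 0)) {
    stop("q has zero mass where p is positive; apply a pseudocount")
  }
  pos <- p > 0
  sum(p[pos] * log(p[pos] / q[pos]))
}

#' Differential-conservation profile of a grouped alignment
#'
#' Scores every alignment column by the Kullback-Leibler divergence
#' between the two groups' amino-acid frequency distributions. Scores are
#' high for positions conserved within each group but at different
#' residues, and low for positions that are either variable or conserved
#' identically across both groups.
#'
#' The KL direction is configurable (the divergence is asymmetric); the
#' default takes `p` from group `b` and `q` from group `a`, matching a
#' setup where `a` holds the trafficking isoforms and `b` the
#' non-trafficking ones, and a symmetrized Jensen-Shannon variant is
#' available. The direction used is recorded in the result.
#'
#' @param grouped A [split_alignment()] result.
#' @param pseudocount Smoothing constant per group; default `1 / n_group`
#'   (scale-aware Laplace). For exact invariance under duplicating a
#'   group's sequences, hold the pseudocount proportional to group size.
#' @param direction `"b_vs_a"` (default; `KL(freq_b || freq_a)`),
#'   `"a_vs_b"`, or `"symmetric"` (Jensen-Shannon divergence).
#' @param reference Optional sequence id used to map columns to residue
#'   numbers by ungapped-position counting.
#' @param gap_flag_fraction Columns with more than this gap fraction in
#'   either group are flagged `majority_gap`; all-gap columns are flagged
#'   `all_gap` and score `NA`.
#' @return Object of class `conservation_profile`: a `data.frame` with
#'   `column` (1-based alignment coordinates), `ref_residue` (or `NA`),
#'   `kldiv`, `gap_fraction_a`, `gap_fraction_b`, `flag`; frequency
#'   matrices in attributes `freq_a`, `freq_b`; direction in attribute
#'   `direction`.
#' @export
kldiv_profile <- function(grouped, pseudocount = NULL,
                          direction = c("b_vs_a", "a_vs_b", "symmetric"),
                          reference = NULL, gap_flag_fraction = 0.5) {
  stopifnot(inherits(grouped, "grouped_alignment"))
  direction <- match.arg(direction)
  nc <- ncol(grouped$a)
  eps_a <- if (is.null(pseudocount)) 1 / nrow(grouped$a) else pseudocount
  eps_b <- if (is.null(pseudocount)) 1 / nrow(grouped$b) else pseudocount

  freq_a <- t(vapply(seq_len(nc), function(j)
    column_frequencies(grouped$a, j, eps_a), numeric(20)))
  freq_b <- t(vapply(seq_len(nc), function(j)
    column_frequencies(grouped$b, j, eps_b), numeric(20)))

  gap_a <- colMeans(!matrix(grouped$a %in% .AA, nrow(grouped$a)))
  gap_b <- colMeans(!matrix(grouped$b %in% .AA, nrow(grouped$b)))

  kld <- vapply(seq_len(nc), function(j) {
    p <- switch(direction, b_vs_a = freq_b[j, ], a_vs_b = freq_a[j, ],
                symmetric = freq_a[j, ])
    q <- switch(direction, b_vs_a = freq_a[j, ], a_vs_b = freq_b[j, ],
                symmetric = freq_b[j, ])
    if (anyNA(p) || anyNA(q)) return(NA_real_)
    if (direction == "symmetric") {
      m <- (p + q) / 2
      0.5 * kl_divergence(p, m) + 0.5 * kl_divergence(q, m)
    } else {
      kl_divergence(p, q)
    }
  }, numeric(1))

  flag <- rep("", nc)
  flag[gap_a > gap_flag_fraction | gap_b > gap_flag_fraction] <- "majority_gap"
  flag[gap_a == 1 | gap_b == 1] <- "all_gap"

  ref_residue <- rep(NA_integer_, nc)
  if (!is.null(reference)) {
    full <- rbind(grouped$a, grouped$b)
    if (!reference %in% rownames(full)) {
      stop("reference sequence '", reference, "' not in alignment")
    }
    rseq <- full[reference, ]
    isres <- rseq %in% .AA
    ref_residue[isres] <- cumsum(isres)[isres]
  }

  out <- data.frame(
    column = seq_len(nc) + grouped$offset - 1L,
    ref_residue = ref_residue,
    kldiv = kld,
    gap_fraction_a = gap_a,
    gap_fraction_b = gap_b,
    flag = flag,
    stringsAsFactors = FALSE)
  attr(out, "freq_a") <- freq_a
  attr(out, "freq_b") <- freq_b
  attr(out, "direction") <- direction
  attr(out, "group_names") <- grouped$group_names
  class(out) <- c("conservation_profile", "data.frame")
  out
}

#' @export
print.conservation_profile <- function(x, n = 10, ...) {
  cat(sprintf("Differential conservation profile: %d columns (%s; nats)\n",
              nrow(x), attr(x, "direction")))
  top <- x[order(-x$kldiv), ][seq_len(min(n, nrow(x))), ]
  cat("Top-scoring columns:\n")
  print(format(as.data.frame(top)[, c("column", "ref_residue", "kldiv", "flag")],
               digits = 3), row.names = FALSE)
  invisible(x)
}

#' @method plot conservation_profile
#' @export
plot.conservation_profile <- function(x, ...) {
  graphics::barplot(x$kldiv, names.arg = x$column,
                    xlab = "Alignment column", ylab = "KLdiv (nats)",
                    border = NA, ...)
  invisible(x)
}
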