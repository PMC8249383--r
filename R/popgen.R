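#' Nucleotide diversity and Watterson's theta from a coding alignment
#'
#' Per-site estimates from an aligned sample of n >= 2 sequences. Columns
#' containing a gap, N, or any other ambiguity in any sequence are excluded
#' (complete deletion), leaving L_used sites. S counts retained columns with
#' at least two distinct bases (multi-allelic columns count once); pi is the
#' mean pairwise difference per retained site,
#' sum_(i<j) d_ij / (C(n,2) * L_used); theta_W = S / (a_n * L_used) with
#' a_n = sum_(i=1)^(n-1) 1/i.
#'
#' @param aln character vector of aligned sequences (equal lengths), e.g.
#'   from [read_fasta()] on a multi-FASTA alignment.
#' @return list of class `diversity_estimates` with elements pi, theta_w, S,
#'   n, L_total, L_used, a_n.
#' @export
diversity <- function(aln) {
  aln <- toupper(unname(unlist(aln)))
  n <- length(aln)
  if (n < 2L) stop("need at least two sequences", call. = FALSE)
  lens <- nchar(aln)
  if (length(unique(lens)) != 1L)
    stop("aligned sequences must have equal length", call. = FALSE)
  m <- do.call(rbind, strsplit(gsub("U", "T", aln, fixed = TRUE), "",
                               fixed = TRUE))
  usable <- colSums(matrix(m %in% DNA_BASES, nrow = n)) == n
  L_used <- sum(usable)
  if (L_used == 0L)
    stop("diversity undefined: no usable alignment columns", call. = FALSE)
  mu <- m[, usable, drop = FALSE]
  S <- sum(apply(mu, 2, function(col) length(unique(col))) > 1L)
  dsum <- 0
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      dsum <- dsum + sum(mu[i, ] != mu[j, ])
    }
  }
  a_n <- sum(1 / seq_len(n - 1L))
  structure(list(pi = dsum / (choose(n, 2) * L_used),
                 theta_w = S / (a_n * L_used),
                 S = as.integer(S), n = as.integer(n),
                 L_total = as.integer(lens[1]), L_used = as.integer(L_used),
                 a_n = a_n),
            class = "diversity_estimates")
}

#' @export
print.diversity_estimates <- function(x, digits = 4, ...) {
  cat(sprintf("Diversity estimates (n = %d, %d/%d sites used)\n",
              x$n, x$L_used, x$L_total))
  cat(sprintf("  pi      = %s\n  theta_W = %s\n  S       = %d  (a_n = %.4f)\n",
              format(round(x$pi, digits)), format(round(x$theta_w, digits)),
              x$S, x$a_n))
  invisible(x)
}

#' Proportion estimate with a binomial confidence interval
#'
#' Small helper for screen tallies (e.g. the fraction of tetraploids among
#' screened F2 offspring): point estimate and exact binomial CI.
#'
#' @param n_event number of positives.
#' @param n_total number screened.
#' @param conf.level confidence level.
#' @return list with estimate (proportion), percent, conf.int, n_event,
#'   n_total.
#' @export
screen_proportion <- function(n_event, n_total, conf.level = 0.95) {
  bt <- stats::binom.test(n_event, n_total, conf.level = conf.level)
  list(estimate = unname(bt$estimate), percent = unname(bt$estimate) * 100,
       conf.int = as.numeric(bt$conf.int),
       n_event = n_event, n_total = n_total)
}
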