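#' Equivalent change index (ECI)
#'
#' The ECI compares the log2 fold changes of a gene between two
#' treatment-vs-control contrasts.  It is the ratio of the smaller to the
#' larger absolute effect, signed by whether the two effects agree, and
#' damped by the less reliable of the two p-values:
#' \deqn{\lambda = \mathrm{sign}(\beta_1\beta_2)\,
#'   \frac{\min(|\beta_1|,|\beta_2|)}{\max(|\beta_1|,|\beta_2|)}\,
#'   (1 - \max(p_1, p_2)).}
#' It lies in \[-1, 1\]: +1 means exactly equivalent change in both
#' contrasts (e.g. doubled in both), -1 exactly inverse change (halved in
#' one, doubled in the other), 0 no usable evidence (an effect of zero in
#' either contrast, or a p-value of 1).
#'
#' @param beta1,beta2 Numeric vectors of log2 fold changes, one per contrast.
#' @param p1,p2 Numeric vectors of p-values in \[0, 1\].
#' @return A numeric vector of ECIs in \[-1, 1\], recycled to the common
#'   length of the inputs.
#' @examples
#' compute_eci(-1, 0, 1, 0)          # exactly inverse: -1
#' compute_eci(2, 0.1, 1, 0.2)       # (1/2) * 0.8 = 0.4
#' @export
compute_eci <- function(beta1, p1, beta2, p2) {
  n <- max(length(beta1), length(p1), length(beta2), length(p2))
  beta1 <- rep_len(beta1, n); beta2 <- rep_len(beta2, n)
  p1 <- rep_len(p1, n); p2 <- rep_len(p2, n)
  if (!all(is.finite(beta1)) || !all(is.finite(beta2))) {
    stop_input("log2 fold changes must be finite")
  }
  if (!all(is_prob(p1)) || !all(is_prob(p2))) {
    stop_input("p-values must be finite and in [0, 1]")
  }
  lo <- pmin(abs(beta1), abs(beta2))
  hi <- pmax(abs(beta1), abs(beta2))
  ratio <- ifelse(hi == 0, 0, lo / hi)   # both betas 0: define 0/0 as 0
  sign(beta1 * beta2) * ratio * (1 - pmax(p1, p2))
}

#' Standardize ECIs with respect to the whole data set
#'
#' Centers and scales the full ECI vector, then multiplies by the sign of
#' the direction of interest so that genes changed in the direction under
#' study get positive standardized values.  These standardized values are
#' the experimental term of the module score ([score_network()]).
#'
#' @param eci Numeric vector of ECIs (the entire data set, not a module).
#' @param s Direction of interest: `+1` for equivalent change, `-1` for
#'   inverse change.
#' @return Numeric vector `s * (eci - mean(eci)) / sd(eci)`.
#' @export
standardize_eci <- function(eci, s = 1) {
  if (!s %in% c(-1, 1)) stop_input("`s` must be +1 or -1")
  if (length(eci) < 2) stop_input("need at least 2 ECIs to standardize")
  sdev <- sd(eci)
  if (!is.finite(sdev) || sdev == 0) {
    stop_input("ECIs have zero variance; cannot standardize")
  }
  s * (eci - mean(eci)) / sdev
}

#' Restart distribution for random walk with restart
#'
#' Builds the non-negative, unit-sum seed vector from ECIs.  A gene in the
#' direction of interest (DOI) is seeded proportionally to `|eci|`; a gene
#' changed against the DOI still carries more prior relevance than a gene
#' with no change, so it is seeded at `c * |eci|` with `c` in \[0, 1\]:
#' \deqn{p_{0i} \propto |e_i| I(s e_i > 0) + c\,|e_i| (1 - I(s e_i > 0)).}
#' With `s = -1` and `c = 0.5`, a gene with ECI `+x` receives exactly half
#' the seed weight of a gene with ECI `-x`.
#'
#' @param eci Numeric vector of ECIs, aligned to (and optionally named by)
#'   the current network's nodes.
#' @param s Direction of interest, `+1` or `-1`.
#' @param c Relative weight for genes not in the DOI, in \[0, 1\].
#' @return Numeric vector of the same length, non-negative, summing to 1.
#' @export
seed_vector <- function(eci, s = 1, c = 0.5) {
  if (!s %in% c(-1, 1)) stop_input("`s` must be +1 or -1")
  assert_scalar_prob(c, "c")
  if (!length(eci) || !all(is.finite(eci))) {
    stop_input("ECIs must be a non-empty finite vector")
  }
  w <- abs(eci) * ifelse(s * eci > 0, 1, c)
  tot <- sum(w)
  if (tot == 0) {
    stop_algorithm("all seed weights are zero: no gene carries ECI mass")
  }
  w / tot
}

#' Join two differential-expression contrasts into a gene statistics table
#'
#' Matches genes across two DE summary tables by exact identifier, computes
#' the ECI and its standardized value, and carries an optional significance
#' flag.  This table is the experimental input to [run_amend()].
#'
#' @param de1,de2 Data frames with columns `gene_id`, `log2fc`, `pvalue`
#'   (one per contrast); extra columns are ignored except an optional
#'   logical `significant`, which is combined across contrasts with `&`.
#' @param s Direction of interest, `+1` (equivalent) or `-1` (inverse).
#' @return A tibble with columns `gene_id`, `beta1`, `p1`, `beta2`, `p2`,
#'   `eci`, `z` and (when available) `significant`, one row per gene
#'   present in both contrasts.
#' @export
prepare_gene_stats <- function(de1, de2, s = -1) {
  need <- c("gene_id", "log2fc", "pvalue")
  for (d in list(de1, de2)) {
    if (!all(need %in% names(d))) {
      stop_input("DE tables need columns gene_id, log2fc, pvalue")
    }
  }
  d1 <- tibble::as_tibble(de1)[unique(c(need, intersect("significant", names(de1))))]
  d2 <- tibble::as_tibble(de2)[unique(c(need, intersect("significant", names(de2))))]
  joined <- dplyr::inner_join(d1, d2, by = "gene_id", suffix = c("1", "2"))
  if (nrow(joined) == 0) stop_input("no genes shared between the two contrasts")
  out <- tibble::tibble(
    gene_id = joined$gene_id,
    beta1 = joined$log2fc1, p1 = joined$pvalue1,
    beta2 = joined$log2fc2, p2 = joined$pvalue2
  )
  out$eci <- compute_eci(out$beta1, out$p1, out$beta2, out$p2)
  out$z <- standardize_eci(out$eci, s = s)
  if (all(c("significant1", "significant2") %in% names(joined))) {
    out$significant <- joined$significant1 & joined$significant2
  } else if ("significant1" %in% names(joined)) {
    out$significant <- joined$significant1
  } else if ("significant2" %in% names(joined)) {
    out$significant <- joined$significant2
  }
  out
}
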