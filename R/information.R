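#' Signal-to-noise ratio of cyclewise vesicle counts
#'
#' At each contrast the SNR is the squared trial-mean vesicle count divided by
#' the across-trial variance, \eqn{SNR = S^2 / \sigma^2}. The variance is the
#' unbiased (n - 1) estimator by default. A contrast whose trials are all
#' identical has zero variance; its SNR is reported as infinite and flagged
#' rather than raising an error.
#'
#' @param counts a [count_per_cycle()] result, or a numeric vector of per-trial
#'   vesicle counts at a single contrast.
#' @param contrast restrict to one contrast (required when `counts` covers
#'   several and a single entry is wanted); by default all contrasts are
#'   reported.
#' @param var_estimator `"unbiased"` (n - 1, default) or `"ml"` (n).
#' @return an `snr_result` data frame with columns `contrast`, `S` (mean
#'   vesicles per cycle), `sigma2`, `snr`, `n_trials`, `degenerate` (TRUE when
#'   the variance is zero).
#' @examples
#' snr(c(2, 4))   # S = 3, sigma2 = 2, SNR = 4.5
#' @export
snr <- function(counts, contrast = NULL,
                var_estimator = c("unbiased", "ml")) {
  var_estimator <- match.arg(var_estimator)
  if (is.numeric(counts)) {
    counts <- structure(
      data.frame(contrast = if (is.null(contrast)) NA_real_ else contrast,
                 vesicles = counts),
      class = c("cyclewise_counts", "data.frame"))
    contrast <- NULL
  }
  df <- as.data.frame(counts)
  if (!is.null(contrast)) df <- df[df$contrast %in% contrast, ]
  sp <- split(df$vesicles, factor(df$contrast, exclude = NULL))
  out <- do.call(rbind, lapply(seq_along(sp), function(i) {
    cc <- names(sp)[i]
    v <- sp[[i]]
    if (length(v) < 2L)
      stop("SNR needs >= 2 trials at contrast ", cc)
    S <- mean(v)
    s2 <- if (var_estimator == "unbiased") stats::var(v)
    else mean((v - S)^2)
    data.frame(contrast = suppressWarnings(as.numeric(cc)), S = S, sigma2 = s2,
               snr = if (s2 > 0) S^2 / s2 else Inf,
               n_trials = length(v), degenerate = s2 == 0)
  }))
  rownames(out) <- NULL
  structure(out, class = c("snr_result", "data.frame"))
}

#' Bin a quantal series into fixed-width time bins
#'
#' Converts the event train into the discrete response alphabet used by the
#' information calculations: time bins of `bin_width` (20 ms by default), each
#' holding the total quanta of the events falling in it, aligned to stimulus
#' cycles (the bin width must divide the cycle duration; 20-ms bins tile a
#' 200-ms cycle in 10). At this width a bin should contain at most one event;
#' bins holding two or more are flagged (their quanta are summed into one
#' symbol) and the violation rate is recorded.
#'
#' @param series a [quantal_series()].
#' @param protocol a [make_stimulus()] protocol.
#' @param bin_width bin width in seconds (default 0.02).
#' @return a `binned_response`: data frame with `cycle`, `contrast`, `bin`
#'   (index within cycle), `q` (quanta in bin), `n_events`, `flagged`;
#'   attributes `bin_width`, `bins_per_cycle`, `violation_rate`, `frequency`.
#' @export
bin_events <- function(series, protocol, bin_width = 0.02) {
  stopifnot(inherits(series, "quantal_series"),
            inherits(protocol, "stimulus_protocol"), bin_width > 0)
  ratio <- protocol$cycle_duration / bin_width
  if (abs(ratio - round(ratio)) > 1e-9) {
    divisors <- protocol$cycle_duration / seq_len(50)
    stop(sprintf(
      "bin_width %g s does not divide the %g s cycle; try one of: %s",
      bin_width, protocol$cycle_duration,
      paste(signif(utils::head(divisors, 8), 3), collapse = ", ")))
  }
  bpc <- as.integer(round(ratio))
  n_bins <- bpc * protocol$n_cycles
  q <- integer(n_bins); nev <- integer(n_bins)
  if (length(series$times)) {
    if (any(series$times < 0 | series$times >= protocol$duration))
      stop("events outside the protocol duration")
    gbin <- as.integer(floor(series$times / bin_width)) + 1L
    for (i in seq_along(gbin)) {
      q[gbin[i]] <- q[gbin[i]] + series$quanta[i]
      nev[gbin[i]] <- nev[gbin[i]] + 1L
    }
  }
  cyc <- rep(seq_len(protocol$n_cycles), each = bpc)
  df <- data.frame(cycle = cyc,
                   contrast = protocol$contrasts[cyc],
                   bin = rep(seq_len(bpc), protocol$n_cycles),
                   q = q, n_events = nev, flagged = nev >= 2L)
  structure(df, class = c("binned_response", "data.frame"),
            bin_width = bin_width, bins_per_cycle = bpc,
            violation_rate = mean(nev >= 2L),
            frequency = protocol$frequency)
}

#' Empirical stimulus/response distributions from binned responses
#'
#' Builds the plug-in probability tables that the information measures are
#' computed from: the conditional distribution of the per-bin quantal count Q
#' given the stimulus contrast S (bin-type frequencies within each contrast),
#' the designed stimulus marginal p(S) (taken from the protocol, exactly
#' uniform for an equiprobable design, rather than re-estimated), the joint
#' p(S,Q) = p(Q|S) p(S), the response marginal p(Q) and the posterior
#' p(S|Q) = p(S,Q) / p(Q).
#'
#' @param binned a [bin_events()] result.
#' @param protocol the matching protocol.
#' @return an `info_distributions` object: list of matrices/vectors
#'   `p_q_given_s` (S x Q), `p_s`, `p_sq`, `p_q`, `p_s_given_q`, with
#'   stimulus levels as rows and quantal symbols (0, 1, 2, ...) as columns.
#' @export
estimate_distributions <- function(binned, protocol) {
  stopifnot(inherits(binned, "binned_response"))
  s_levels <- sort(unique(protocol$contrasts))
  q_levels <- 0:max(binned$q)
  tab <- table(factor(binned$contrast, levels = s_levels),
               factor(binned$q, levels = q_levels))
  if (any(rowSums(tab) == 0))
    stop("a stimulus contrast has zero bins; cannot form p(Q|S)")
  p_q_given_s <- sweep(unclass(tab), 1, rowSums(tab), "/")
  p_s <- as.numeric(table(factor(protocol$contrasts, levels = s_levels))) /
    protocol$n_cycles
  names(p_s) <- as.character(s_levels)
  p_sq <- p_q_given_s * p_s
  p_q <- colSums(p_sq)
  p_s_given_q <- sweep(p_sq, 2, ifelse(p_q > 0, p_q, 1), "/")
  structure(list(p_q_given_s = p_q_given_s, p_s = p_s, p_sq = p_sq,
                 p_q = p_q, p_s_given_q = p_s_given_q,
                 s_levels = s_levels, q_levels = q_levels),
            class = "info_distributions")
}

#' Build information distributions from explicit tables
#'
#' Lower-level constructor for [mutual_information()] and
#' [specific_information()] when the conditional table and stimulus marginal
#' are known directly (e.g. an analytic channel).
#'
#' @param p_q_given_s matrix, rows = stimuli, columns = response symbols; each
#'   row sums to 1.
#' @param p_s stimulus marginal, one entry per row.
#' @return an `info_distributions` object.
#' @export
info_distributions <- function(p_q_given_s, p_s) {
  p_q_given_s <- as.matrix(p_q_given_s)
  stopifnot(nrow(p_q_given_s) == length(p_s),
            all(p_q_given_s >= 0), all(p_s >= 0))
  if (max(abs(rowSums(p_q_given_s) - 1)) > 1e-9)
    stop("rows of p_q_given_s must sum to 1")
  if (abs(sum(p_s) - 1) > 1e-9) stop("p_s must sum to 1")
  p_sq <- p_q_given_s * p_s
  p_q <- colSums(p_sq)
  p_s_given_q <- sweep(p_sq, 2, ifelse(p_q > 0, p_q, 1), "/")
  q_levels <- colnames(p_q_given_s)
  if (is.null(q_levels)) q_levels <- seq_len(ncol(p_q_given_s)) - 1L
  structure(list(p_q_given_s = p_q_given_s, p_s = p_s, p_sq = p_sq,
                 p_q = p_q, p_s_given_q = p_s_given_q,
                 s_levels = rownames(p_q_given_s) %||% seq_along(p_s),
                 q_levels = q_levels),
            class = "info_distributions")
}

# Shannon entropy in bits with the 0 log 0 = 0 convention.
entropy_bits <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Mutual information between stimulus and binned response
#'
#' Plug-in estimate, in bits per bin, from the joint distribution:
#' \deqn{I(S;Q) = \sum_s \sum_q p(s,q) \log_2 \frac{p(s,q)}{p(s)\,p(q)},}
#' with `0 log 0 = 0`. Symmetric in S and Q; equals `H(S) - H(S|Q)`.
#'
#' @param dists an `info_distributions` object.
#' @return mutual information in bits (per bin of the binned alphabet).
#' @export
mutual_information <- function(dists) {
  stopifnot(inherits(dists, "info_distributions"))
  p_sq <- dists$p_sq
  outer_p <- outer(dists$p_s, dists$p_q)
  nz <- p_sq > 0
  sum(p_sq[nz] * log2(p_sq[nz] / outer_p[nz]))
}

#' Specific information carried by each response symbol
#'
#' For each response symbol q with p(q) > 0,
#' \deqn{I_2(S; q) = H(S) - H(S | q)
#'   = -\sum_s p(s)\log_2 p(s) + \sum_s p(s|q)\log_2 p(s|q):}
#' the reduction in stimulus uncertainty from observing that particular
#' symbol. Individual values may be negative; their p(q)-weighted mean is the
#' mutual information.
#'
#' @param dists an `info_distributions` object.
#' @return data frame with `q` (symbol), `p_q`, `I2_bits`; symbols with
#'   p(q) = 0 are omitted (with a message).
#' @export
specific_information <- function(dists) {
  stopifnot(inherits(dists, "info_distributions"))
  hs <- entropy_bits(dists$p_s)
  keep <- dists$p_q > 0
  if (any(!keep))
    message("omitting ", sum(!keep), " response symbol(s) with p(q) = 0")
  i2 <- vapply(which(keep), function(j) {
    hs - entropy_bits(dists$p_s_given_q[, j])
  }, numeric(1))
  data.frame(q = dists$q_levels[keep],
             p_q = unname(dists$p_q[keep]),
             I2_bits = unname(i2))
}

#' Entropies of an information-distribution object
#' @param dists an `info_distributions` object.
#' @return named vector: `H_S`, `H_Q`, `H_S_given_Q`, all in bits.
#' @export
info_entropies <- function(dists) {
  hs <- entropy_bits(dists$p_s)
  hq <- entropy_bits(dists$p_q)
  hsq <- entropy_bits(dists$p_sq)
  c(H_S = hs, H_Q = hq, H_S_given_Q = hsq - hq)
}

#' Convert per-cycle information to an information rate
#'
#' @param bits_per_cycle information in bits per stimulus cycle.
#' @param frequency stimulus frequency in Hz.
#' @return bits per second.
#' @examples
#' information_rate(log2(11), 5)   # 17.3 bits/s
#' @export
information_rate <- function(bits_per_cycle, frequency) {
  stopifnot(frequency > 0)
  bits_per_cycle * frequency
}

#' Full information report for a quantal series under a protocol
#'
#' Bins the series, estimates the distributions and reports mutual
#' information, specific information and entropies, on both per-bin and
#' per-cycle/per-second scales. Per-cycle information is, by default, the sum
#' of the per-bin information over the bins of a cycle (`aggregation =
#' "sum_bins"`); the alternative `"cycle_symbol"` treats the total quanta in a
#' cycle as one response symbol and computes I on that alphabet.
#'
#' @param series a [quantal_series()].
#' @param protocol a [make_stimulus()] protocol.
#' @param bin_width bin width in seconds (default 0.02).
#' @param aggregation `"sum_bins"` (default) or `"cycle_symbol"`.
#' @return an `info_result`: list with `I_bits_per_bin`, `I_bits_per_cycle`,
#'   `I_bits_per_s`, `H_S`, `entropies`, `specific` (data frame),
#'   `violation_rate`, `dists`, `aggregation`.
#' @export
information_report <- function(series, protocol, bin_width = 0.02,
                               aggregation = c("sum_bins", "cycle_symbol")) {
  aggregation <- match.arg(aggregation)
  binned <- bin_events(series, protocol, bin_width)
  dists <- estimate_distributions(binned, protocol)
  i_bin <- mutual_information(dists)
  bpc <- attr(binned, "bins_per_cycle")
  if (aggregation == "sum_bins") {
    i_cycle <- i_bin * bpc
  } else {
    per_cycle <- stats::aggregate(q ~ cycle + contrast, data = binned,
                                  FUN = sum)
    s_levels <- sort(unique(protocol$contrasts))
    q_levels <- 0:max(per_cycle$q)
    tab <- table(factor(per_cycle$contrast, levels = s_levels),
                 factor(per_cycle$q, levels = q_levels))
    pq_s <- sweep(unclass(tab), 1, pmax(rowSums(tab), 1), "/")
    p_s <- as.numeric(table(factor(protocol$contrasts, levels = s_levels))) /
      protocol$n_cycles
    i_cycle <- mutual_information(info_distributions(pq_s, p_s))
  }
  ents <- info_entropies(dists)
  structure(list(I_bits_per_bin = i_bin,
                 I_bits_per_cycle = i_cycle,
                 I_bits_per_s = information_rate(i_cycle, protocol$frequency),
                 H_S = unname(ents["H_S"]),
                 entropies = ents,
                 specific = specific_information(dists),
                 violation_rate = attr(binned, "violation_rate"),
                 dists = dists,
                 aggregation = aggregation),
            class = "info_result")
}

#' @export
print.info_result <- function(x, ...) {
  cat(sprintf(
    "Information report (%s): %.4g bits/bin, %.4g bits/cycle, %.4g bits/s (H(S) = %.3f bits)\n",
    x$aggregation, x$I_bits_per_bin, x$I_bits_per_cycle, x$I_bits_per_s,
    x$H_S))
  invisible(x)
}

#' Shuffle-null diagnostic for the plug-in information estimate
#'
#' Recomputes the mutual information after randomly permuting the stimulus
#' labels of the bins, which destroys any stimulus-response association; the
#' distribution of shuffled values estimates the small-sample (limited
#' sampling) bias of the plug-in estimator.
#'
#' @param binned a [bin_events()] result.
#' @param protocol the matching protocol.
#' @param n_shuffles number of permutations (default 20).
#' @param seed integer seed.
#' @return named vector: `I_shuffled_mean`, `I_shuffled_sd` (bits per bin).
#' @export
shuffle_null_information <- function(binned, protocol, n_shuffles = 20L,
                                     seed = 1L) {
  stopifnot(inherits(binned, "binned_response"))
  vals <- withr_seed(seed, vapply(seq_len(n_shuffles), function(i) {
    b2 <- binned
    b2$contrast <- sample(binned$contrast)
    mutual_information(estimate_distributions(b2, protocol))
  }, numeric(1)))
  c(I_shuffled_mean = mean(vals), I_shuffled_sd = stats::sd(vals))
}
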