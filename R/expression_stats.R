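# Comparative-CT relative expression and small summary statistics.

#' Simulate a qPCR Ct panel with a known fold change
#'
#' Two groups of samples (calibrator/control and treated) measured for a
#' target gene and a reference gene (the role of Actb). The treated target
#' Ct is offset by `-log2(true_fold_change)` relative to the calibrator
#' after reference normalisation, plus Gaussian noise on every Ct, so
#' [delta_delta_ct()] recovers `true_fold_change` exactly at zero noise.
#'
#' @param true_fold_change generating fold change (> 0).
#' @param n_replicates samples per group.
#' @param noise_sd Gaussian Ct noise, cycles (>= 0).
#' @param seed optional integer seed.
#' @param target,reference gene labels.
#' @param base_ct_target,base_ct_reference baseline Ct values (cycles).
#' @return A `ct_panel`: list with `data` (data.frame `sample, group, gene,
#'   ct`), `target`, `reference`, `calibrator_group`.
#' @export
simulate_ct_panel <- function(true_fold_change, n_replicates = 3L,
                              noise_sd = 0.2, seed = NULL,
                              target = "target", reference = "Actb",
                              base_ct_target = 25, base_ct_reference = 17) {
  if (true_fold_change <= 0) stop("fold change must be positive")
  stopifnot(n_replicates >= 1, noise_sd >= 0)
  with_seed_or_not(seed, {
    groups <- rep(c("control", "treated"), each = n_replicates)
    sample_id <- paste0(groups, "_", rep(seq_len(n_replicates), 2L))
    shift <- ifelse(groups == "treated", -log2(true_fold_change), 0)
    n <- length(sample_id)
    d <- rbind(
      data.frame(sample = sample_id, group = groups, gene = target,
                 ct = base_ct_target + shift + rnorm(n, 0, noise_sd)),
      data.frame(sample = sample_id, group = groups, gene = reference,
                 ct = base_ct_reference + rnorm(n, 0, noise_sd)))
    structure(list(data = d, target = target, reference = reference,
                   calibrator_group = "control"), class = "ct_panel")
  })
}

#' Construct a Ct panel from raw data
#'
#' @param data data.frame with columns `sample, group, gene, ct` (replicate
#'   wells may repeat a sample/gene combination; they are averaged).
#' @param target,reference gene names; the reference must be measured in
#'   every sample.
#' @param calibrator_group group label used as the calibrator.
#' @return A `ct_panel`.
#' @export
ct_panel <- function(data, target, reference, calibrator_group) {
  stopifnot(all(c("sample", "group", "gene", "ct") %in% names(data)))
  if (any(!is.finite(data$ct))) stop("all Ct values must be finite")
  if (!all(c(target, reference) %in% data$gene))
    stop("target and reference genes must be present")
  samples <- unique(data$sample)
  has_ref <- vapply(samples, function(s)
    any(data$sample == s & data$gene == reference), logical(1))
  if (!all(has_ref)) stop("reference gene missing in some samples")
  if (!calibrator_group %in% data$group) stop("calibrator group not present")
  structure(list(data = data, target = target, reference = reference,
                 calibrator_group = calibrator_group), class = "ct_panel")
}

#' Comparative-CT (2^-ddCt) relative expression
#'
#' Per sample, replicate Cts are averaged arithmetically, then
#' `dCt = Ct_target - Ct_reference`; `ddCt` subtracts the calibrator-group
#' mean dCt; the fold change is `2^-ddCt`. The calibrator group's geometric
#' mean fold is 1 by construction.
#'
#' @param panel a `ct_panel` ([simulate_ct_panel()] or [ct_panel()]).
#' @return list with `samples` (data.frame `sample, group, dct, ddct,
#'   fold`) and `group_fold` (named vector of per-group geometric mean
#'   folds).
#' @examples
#' p <- simulate_ct_panel(15, noise_sd = 0, seed = 1)
#' delta_delta_ct(p)$group_fold
#' @export
delta_delta_ct <- function(panel) {
  stopifnot(inherits(panel, "ct_panel"))
  d <- panel$data
  mean_ct <- function(s, g) {
    v <- d$ct[d$sample == s & d$gene == g]
    if (!length(v)) stop("missing Ct for sample ", s, ", gene ", g)
    mean(v)
  }
  samples <- unique(d$sample)
  group <- d$group[match(samples, d$sample)]
  dct <- vapply(samples, function(s)
    mean_ct(s, panel$target) - mean_ct(s, panel$reference), numeric(1))
  cal <- mean(dct[group == panel$calibrator_group])
  ddct <- dct - cal
  fold <- 2^(-ddct)
  res <- data.frame(sample = samples, group = group, dct = dct, ddct = ddct,
                    fold = fold, stringsAsFactors = FALSE)
  rownames(res) <- NULL
  gf <- vapply(split(res$fold, res$group), function(f)
    exp(mean(log(f))), numeric(1))
  list(samples = res, group_fold = gf)
}

#' Describe a group by its summary statistics
#'
#' @param label group label.
#' @param mean group mean.
#' @param dispersion dispersion value (>= 0).
#' @param n group size (>= 2).
#' @param kind `"sd"` or `"sem"`; SEM is converted to SD via
#'   `sd = sem * sqrt(n)` where needed.
#' @return A `summary_group` list.
#' @export
summary_group <- function(label, mean, dispersion, n, kind = c("sd", "sem")) {
  kind <- match.arg(kind)
  stopifnot(n >= 2, dispersion >= 0, is.finite(mean))
  structure(list(label = label, mean = mean, dispersion = dispersion,
                 n = as.integer(n), kind = kind), class = "summary_group")
}

#' Two-sample t-test from group summary statistics
#'
#' Standard Student (pooled-variance) or Welch t-test computed from means,
#' dispersions and group sizes, for published tables that report only
#' summaries. Degenerate inputs are handled explicitly: zero dispersion in
#' both groups gives t = 0 (equal means; p = 1 or 0.5 by tails) or p -> 0
#' (unequal means), flagged in `note`.
#'
#' @param a,b [summary_group()] objects.
#' @param variant `"student"` (pooled, the default) or `"welch"`.
#' @param tails 1 or 2. The one-tailed p tests the observed direction:
#'   `P(T >= |t| observed direction)`, equal to half the two-tailed p when
#'   the direction matches.
#' @return list `t, df, p, variant, tails, significant` (p < 0.05), `note`.
#' @examples
#' a <- summary_group("gfp", 60.15, 10.41, 3)
#' b <- summary_group("wt", 61.63, 4.87, 3)
#' t_test_from_summary(a, b)
#' @export
t_test_from_summary <- function(a, b, variant = c("student", "welch"),
                                tails = 2L) {
  variant <- match.arg(variant)
  stopifnot(inherits(a, "summary_group"), inherits(b, "summary_group"),
            tails %in% c(1L, 2L))
  sd_of <- function(g) if (g$kind == "sem") g$dispersion * sqrt(g$n) else g$dispersion
  s1 <- sd_of(a); s2 <- sd_of(b)
  n1 <- a$n; n2 <- b$n
  dm <- a$mean - b$mean
  note <- NA_character_
  if (s1 == 0 && s2 == 0) {
    if (dm == 0) {
      t <- 0; df <- n1 + n2 - 2L
      p <- if (tails == 2L) 1 else 0.5
      note <- "zero dispersion in both groups with equal means; t undefined, reported as 0"
    } else {
      t <- sign(dm) * Inf; df <- n1 + n2 - 2L; p <- 0
      note <- "zero dispersion with unequal means; p -> 0"
    }
    return(list(t = t, df = df, p = p, variant = variant, tails = tails,
                significant = p < 0.05, note = note))
  }
  if (variant == "student") {
    sp2 <- ((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    v1 <- s1^2 / n1; v2 <- s2^2 / n2
    se <- sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  }
  t <- dm / se
  p <- if (tails == 2L) 2 * pt(-abs(t), df) else pt(-abs(t), df)
  list(t = t, df = df, p = p, variant = variant, tails = tails,
       significant = p < 0.05, note = note)
}

#' Percentage and exact confidence interval from counts
#'
#' Small helper for recomputing printed rates (e.g. embryo thaw survival
#' 89/100, blastocyst formation 45/89) with an exact binomial CI.
#'
#' @param x successes.
#' @param n trials.
#' @param conf_level confidence level (default 0.95).
#' @return list `percent, ci_lower, ci_upper` (all in percent), `x, n`.
#' @examples
#' rate_from_counts(89, 100)$percent
#' @export
rate_from_counts <- function(x, n, conf_level = 0.95) {
  stopifnot(n >= 1, x >= 0, x <= n)
  bt <- binom.test(x, n, conf.level = conf_level)
  list(percent = 100 * x / n,
       ci_lower = 100 * bt$conf.int[1], ci_upper = 100 * bt$conf.int[2],
       x = x, n = n)
}
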