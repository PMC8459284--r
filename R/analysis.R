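#' Random baselines for the evolved-quantifier measures
#'
#' Two reference samples against which evolved quantifiers are compared:
#' (A) truth tables with independent fair-coin entries, drawn uniformly
#' from all \eqn{2^{2^n}} quantifiers; (B) quantifiers extracted from
#' freshly initialized, untrained agents. Both distributions of the
#' monotonicity degree are heavily skewed toward low values — monotone
#' structure is rare by chance, which is what makes its emergence in
#' chains informative.
#'
#' @param sample_size quantifiers per sample.
#' @param n structure size.
#' @param config optional [agent_config()] for the agent sample.
#' @return A list with `uniform` and `agent`, each a list of
#'   `"quantifier"` objects. Randomness comes from the caller's RNG stream.
#' @export
random_baselines <- function(sample_size, n, config = NULL) {
  n <- .check_n(n)
  stopifnot(sample_size >= 1)
  if (is.null(config)) config <- agent_config(input_size = n)
  uniform <- lapply(seq_len(sample_size), function(s) {
    as_quantifier(runif(2^n) < 0.5, n)
  })
  agent <- lapply(seq_len(sample_size), function(s) {
    extract_quantifier(init_agent(config))
  })
  list(uniform = uniform, agent = agent)
}

#' Classify an evolved quantifier into the recurring pattern types
#'
#' Tests, in order:
#' \enumerate{
#'   \item `degenerate`: a constant truth table.
#'   \item `single_index`: exact match, up to switching 0 and 1 uniformly
#'     in the structures and/or in the outputs, to some ultrafilter
#'     quantifier "bit i is T" — the meaning names one object, like a
#'     proper noun.
#'   \item `two_index_conjunction`: same, for "bits i and j are both T".
#'   \item `threshold_like`: quantitative with a monotone (one-sided
#'     threshold) count table.
#'   \item `other`: everything else. Matching is exact; noisy near-misses
#'     fall here.
#' }
#'
#' @param Q a quantifier.
#' @return A list of class `"pattern_label"` with `label`, `polarity`
#'   (logical `structures`/`outputs` switches of the witnessing match, when
#'   applicable) and `indices` (witnessing 1-based bit positions).
#' @export
classify_pattern <- function(Q) {
  qn <- .check_quantifier(Q)
  q <- qn$table
  n <- qn$n
  res <- function(label, polarity = NULL, indices = integer(0)) {
    structure(list(label = label, polarity = polarity, indices = indices),
              class = "pattern_label")
  }
  if (all(q) || !any(q)) return(res("degenerate"))

  S <- all_structures(n)
  # switching 0/1 in the structures re-indexes the table by bitwise
  # complement; switching in the outputs negates it
  variants <- list(
    list(structures = FALSE, outputs = FALSE, tab = q),
    list(structures = FALSE, outputs = TRUE, tab = !q),
    list(structures = TRUE, outputs = FALSE, tab = rev(q)),
    list(structures = TRUE, outputs = TRUE, tab = rev(!q))
  )
  for (v in variants) {
    for (i in seq_len(n)) {
      if (identical(v$tab, S[, i])) {
        return(res("single_index",
                   polarity = c(structures = v$structures,
                                outputs = v$outputs),
                   indices = i))
      }
    }
  }
  if (n >= 2) {
    for (v in variants) {
      for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
        if (identical(v$tab, S[, i] & S[, j])) {
          return(res("two_index_conjunction",
                     polarity = c(structures = v$structures,
                                  outputs = v$outputs),
                     indices = c(i, j)))
        }
      }
    }
  }
  if (is_quantitative(Q) &&
      (is_monotone(Q, "up") || is_monotone(Q, "down"))) {
    return(res("threshold_like"))
  }
  res("other")
}

#' @export
print.pattern_label <- function(x, ...) {
  cat("<pattern_label> ", x$label,
      if (length(x$indices)) paste0(" (indices ",
                                    paste(x$indices, collapse = ","), ")"),
      "\n", sep = "")
  invisible(x)
}

#' Confidence profile of an agent over count classes
#'
#' Aggregates the agent's raw confidences over all structures with a given
#' number of T bits, for k = 0..n. Proportional-like agents show a mean
#' confidence that rises (or falls) through a threshold count; the
#' dispersion within a count class measures how vague the threshold is.
#'
#' @param agent an agent.
#' @return A tibble with columns `count`, `mean_confidence`,
#'   `sd_confidence` (the chosen dispersion statistic) and `n_structures`.
#' @export
threshold_profile <- function(agent) {
  agent <- .check_agent(agent)
  n <- agent$config$input_size
  conf <- respond(agent, all_structures(n))
  cnt <- .structure_counts(n)
  tibble::tibble(
    count = 0:n,
    mean_confidence = vapply(0:n, function(k) mean(conf[cnt == k]),
                             numeric(1)),
    sd_confidence = vapply(0:n, function(k) {
      v <- conf[cnt == k]
      if (length(v) > 1) sd(v) else 0
    }, numeric(1)),
    n_structures = vapply(0:n, function(k) sum(cnt == k), integer(1))
  )
}

.as_snapshots <- function(snapshots) {
  if (inherits(snapshots, "quantifier_chain")) {
    return(snapshots$snapshots)
  }
  if (is.data.frame(snapshots)) return(snapshots)
  if (is.list(snapshots) &&
      all(vapply(snapshots, inherits, logical(1), "quantifier_chain"))) {
    parts <- lapply(seq_along(snapshots), function(r) {
      s <- snapshots[[r]]$snapshots
      s$run <- r
      s
    })
    return(do.call(rbind, parts))
  }
  stop("snapshots must be a quantifier_chain, a list of them, or their tibble",
       call. = FALSE)
}

#' Summarize chain snapshots into trajectories and pattern shares
#'
#' Produces (a) per-generation trajectories: mean and 95% confidence
#' interval of the monotonicity and quantity degrees plus the share of
#' degenerate quantifiers; and (b) pattern-class shares among the
#' *perfectly monotone, non-degenerate* quantifiers (overall degree exactly
#' 1, which holds precisely for binary-monotone-or-constant tables), both
#' per generation and pooled over the whole input. Degenerate quantifiers
#' are reported separately, never inside the pattern shares.
#'
#' @param snapshots a `"quantifier_chain"`, a list of them, or a snapshot
#'   tibble.
#' @return A list with tibbles `trajectories`, `pattern_shares`
#'   (per generation) and `pattern_shares_pooled`.
#' @export
summarize_run <- function(snapshots) {
  snaps <- .as_snapshots(snapshots)
  if (nrow(snaps) == 0L) stop("no snapshots to summarize", call. = FALSE)

  ci <- function(x) {
    m <- mean(x)
    se <- if (length(x) > 1) sd(x) / sqrt(length(x)) else 0
    c(mean = m, lo = m - 1.96 * se, hi = m + 1.96 * se)
  }
  gens <- sort(unique(snaps$generation))
  traj <- do.call(rbind, lapply(gens, function(g) {
    s <- snaps[snaps$generation == g, ]
    cm <- ci(s$monotonicity); cq <- ci(s$quantity)
    tibble::tibble(
      generation = g, n_agents = nrow(s),
      mean_monotonicity = cm["mean"], mono_ci_lo = cm["lo"],
      mono_ci_hi = cm["hi"],
      mean_quantity = cq["mean"], quant_ci_lo = cq["lo"],
      quant_ci_hi = cq["hi"],
      prop_degenerate = mean(s$degeneracy == 1)
    )
  }))

  # classify each distinct quantifier string once
  labels_for <- function(strings) {
    uq <- unique(strings)
    lab <- vapply(uq, function(s) classify_pattern(as_quantifier(s))$label,
                  character(1))
    lab[match(strings, uq)]
  }
  perfect <- snaps[snaps$monotonicity >= 1 - 1e-12 & snaps$degeneracy < 1, ]
  share_table <- function(s) {
    if (nrow(s) == 0L) {
      return(tibble::tibble(label = character(0), count = integer(0),
                            share = numeric(0)))
    }
    lab <- labels_for(s$quantifier)
    tab <- table(lab)
    tibble::tibble(label = names(tab),
                   count = as.integer(tab),
                   share = as.numeric(tab) / nrow(s))
  }
  per_gen <- do.call(rbind, lapply(gens, function(g) {
    st <- share_table(perfect[perfect$generation == g, ])
    if (nrow(st) == 0L) return(NULL)
    st$generation <- g
    st[, c("generation", "label", "count", "share")]
  }))
  if (is.null(per_gen)) {
    per_gen <- tibble::tibble(generation = integer(0), label = character(0),
                              count = integer(0), share = numeric(0))
  }
  list(
    trajectories = traj,
    pattern_shares = tibble::as_tibble(per_gen),
    pattern_shares_pooled = share_table(perfect)
  )
}
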