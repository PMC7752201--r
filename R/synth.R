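#' Configuration for synthetic sorting studies
#'
#' Defines a generative model of an open-sorting exercise with planted
#' theme structure: `n_quotes` quotes belong to `n_themes` latent themes
#' (the ground truth); each researcher starts from the ground-truth
#' partition as piles and independently perturbs it — one pile split (with
#' probability `p_split`, a random bisection), one pile merge (probability
#' `p_merge`; skipped when only two piles remain, preserving the two-pile
#' rule), then each quote is moved to a uniformly chosen different pile
#' with probability `p_move`. Researchers never see each other's sorts, so
#' perturbations are independent across researchers.
#'
#' The defaults mirror the published study design this generator emulates:
#' 89 quotes sorted by 4 researchers per analyst group around 4 latent
#' themes, with a mild disagreement rate of 0.1 per noise channel.
#'
#' @param n_quotes number of quotes (>= 4).
#' @param n_researchers number of researchers (>= 1).
#' @param n_themes number of planted themes K (>= 2).
#' @param theme_sizes `"balanced"` or an explicit vector of K sizes summing
#'   to `n_quotes`.
#' @param p_move per-quote probability of being moved to another pile.
#' @param p_split probability of one pile-split event per researcher.
#' @param p_merge probability of one pile-merge event per researcher.
#' @param seed integer seed; every quantity generated from the config is a
#'   deterministic function of it.
#' @return Object of class `synthetic_config`.
#' @seealso [generate_study()], [recovery_experiment()]
#' @export
synthetic_config <- function(n_quotes = 89, n_researchers = 4, n_themes = 4,
                             theme_sizes = "balanced", p_move = 0.1,
                             p_split = 0.1, p_merge = 0.1, seed = 0L) {
  n_quotes <- as.integer(n_quotes)
  n_researchers <- as.integer(n_researchers)
  n_themes <- as.integer(n_themes)
  if (n_quotes < 4L) pte_stop("config", "n_quotes must be at least 4")
  if (n_researchers < 1L) pte_stop("config", "n_researchers must be >= 1")
  if (n_themes < 2L) pte_stop("config", "n_themes must be at least 2")
  if (n_themes > n_quotes) {
    pte_stop("config", "more themes than quotes (K = ", n_themes,
             ", N = ", n_quotes, ")")
  }
  if (identical(theme_sizes, "balanced")) {
    sizes <- rep(n_quotes %/% n_themes, n_themes)
    extra <- n_quotes %% n_themes
    if (extra) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  } else {
    sizes <- as.integer(theme_sizes)
    if (length(sizes) != n_themes || any(sizes < 1L) ||
        sum(sizes) != n_quotes) {
      pte_stop("config", "theme_sizes must be ", n_themes,
               " positive sizes summing to ", n_quotes)
    }
  }
  for (p in c(p_move, p_split, p_merge)) {
    if (!is.numeric(p) || p < 0 || p > 1) {
      pte_stop("config", "noise probabilities must lie in [0, 1]")
    }
  }
  structure(list(n_quotes = n_quotes, n_researchers = n_researchers,
                 n_themes = n_themes, theme_sizes = sizes,
                 p_move = p_move, p_split = p_split, p_merge = p_merge,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat("Synthetic sorting config: N =", x$n_quotes, "quotes, R =",
      x$n_researchers, "researchers, K =", x$n_themes, "themes\n")
  cat("  sizes:", paste(x$theme_sizes, collapse = ", "), "\n")
  cat("  p_move =", x$p_move, " p_split =", x$p_split,
      " p_merge =", x$p_merge, " seed =", x$seed, "\n")
  invisible(x)
}

#' Generate a synthetic sorting study with planted themes
#'
#' Draws one study from the generative model described in
#' [synthetic_config()]. Pile labels in the emitted records are the
#' internal pile ids: planted themes keep ids `1..K`, piles created by
#' split events get fresh ids, so with `p_split = p_merge = 0` a quote was
#' moved by a researcher exactly when its pile label differs from its
#' ground-truth theme. A move that would leave a researcher with fewer
#' than two piles is rejected (the quote stays put). Output is fully
#' reproducible from the config seed; researcher sub-streams are derived
#' by fixed offsets.
#'
#' @param config a [synthetic_config()].
#' @return List with `study` (a validated [sorting_study()]) and `truth`
#'   (named grouping vector, canonical labels).
#' @export
generate_study <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  n <- config$n_quotes
  truth <- rep(seq_len(config$n_themes), config$theme_sizes)
  ids <- format_quote_id(seq_len(n))

  records <- lapply(seq_len(config$n_researchers), function(r) {
    pvec <- with_seed(derive_seed(config$seed, r), {
      pv <- truth
      next_id <- config$n_themes + 1L
      # one split event (needs a pile with at least two quotes)
      if (runif(1) < config$p_split) {
        cand <- as.integer(names(which(table(pv) >= 2)))
        if (length(cand)) {
          pile <- cand[sample.int(length(cand), 1L)]
          members <- which(pv == pile)
          take <- sample.int(length(members) - 1L, 1L)
          pv[sample(members, take)] <- next_id
          next_id <- next_id + 1L
        }
      }
      # one merge event (skipped if it would leave a single pile)
      if (runif(1) < config$p_merge && length(unique(pv)) >= 3L) {
        piles <- unique(pv)
        pick <- sample(piles, 2L)
        pv[pv == pick[2L]] <- pick[1L]
      }
      # independent per-quote moves
      for (q in seq_len(n)) {
        if (runif(1) < config$p_move) {
          cur <- pv[q]
          piles <- unique(pv)
          if (sum(pv == cur) == 1L && length(piles) == 2L) next  # rejected
          others <- setdiff(piles, cur)
          pv[q] <- others[sample.int(length(others), 1L)]
        }
      }
      pv
    })
    data.frame(researcher = sprintf("R%d", r), quote = seq_len(n),
               pile = as.character(pvec), stringsAsFactors = FALSE)
  })

  study <- sorting_study(do.call(rbind, records))
  list(study = study,
       truth = setNames(canonical_labels(truth, seq_len(n)), ids))
}

#' Theme-recovery experiment over a configuration grid
#'
#' For each configuration, repeatedly generates a study, builds the
#' co-sort network, detects groupings with [louvain_communities()] and
#' scores them against the planted truth with [adjusted_rand_index()].
#' Replicate seeds (and the Louvain seed of each replicate) are derived
#' deterministically from `seed`, so the whole table is reproducible.
#'
#' @param configs a [synthetic_config()] or list of them.
#' @param replicates replicates per configuration (>= 1).
#' @param seed master seed for the experiment.
#' @param resolution passed to [louvain_communities()].
#' @return Data frame, one row per configuration: the generator parameters
#'   plus `mean_ari`, `sd_ari`, `mean_k` (mean detected grouping count)
#'   and `frac_exact_k` (fraction of replicates recovering exactly K).
#' @export
recovery_experiment <- function(configs, replicates = 20, seed = 0L,
                                resolution = 1) {
  if (inherits(configs, "synthetic_config")) configs <- list(configs)
  if (replicates < 1L) pte_stop("config", "replicates must be >= 1")
  rows <- lapply(seq_along(configs), function(ci) {
    cfg <- configs[[ci]]
    stopifnot(inherits(cfg, "synthetic_config"))
    ari <- numeric(replicates)
    kdet <- integer(replicates)
    for (j in seq_len(replicates)) {
      s <- derive_seed(seed, ci, j)
      cfg_j <- cfg
      cfg_j$seed <- s
      sim <- generate_study(cfg_j)
      net <- build_cosort_network(sim$study)
      asg <- louvain_communities(net, seed = s, resolution = resolution)
      ari[j] <- adjusted_rand_index(asg, sim$truth)
      kdet[j] <- length(unique(asg))
    }
    data.frame(n_quotes = cfg$n_quotes, n_researchers = cfg$n_researchers,
               n_themes = cfg$n_themes, p_move = cfg$p_move,
               p_split = cfg$p_split, p_merge = cfg$p_merge,
               mean_ari = mean(ari),
               sd_ari = if (replicates > 1) sd(ari) else NA_real_,
               mean_k = mean(kdet),
               frac_exact_k = mean(kdet == cfg$n_themes))
  })
  do.call(rbind, rows)
}
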