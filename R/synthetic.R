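#' Configuration of the synthetic coculture world
#'
#' The generator emulates the structure of a pairwise coculture screen:
#' a fixed panel of strains measured against each other across a panel of
#' carbon-source environments, with interaction effects on the log-ratio
#' scale. Each strain carries a latent trait vector; each environment
#' belongs to one of `env_groups` latent archetypes (environments within a
#' group share the archetype, giving the environment redundancy that the
#' similarity-transfer rule exploits); and the continuous effect of sender
#' s on receiver r in environment e is the bilinear form
#' \deqn{E = u_s^\top M_{g(e)}\, u_r / m + \epsilon,\quad
#'   \epsilon \sim N(0, \sigma^2)}
#' with m = `trait_dim` and one random mixing matrix M per archetype.
#' Phylogenetic coordinates are a convex mixture of the traits and
#' independent noise controlled by `phylo_signal`, so at `phylo_signal = 1`
#' phylogeny determines interaction behaviour exactly.
#'
#' Defaults mirror a 20-strain x 40-environment screen with a small
#' fraction of missing wells; see the package vignette for the rationale
#' behind each default.
#'
#' @param n_strains number of strains (>= 2).
#' @param n_environments number of environments (>= 1).
#' @param trait_dim latent trait dimension.
#' @param env_groups number of environment archetypes
#'   (<= `n_environments`).
#' @param noise_sd standard deviation of the effect noise.
#' @param neutral_band half-width of the effect band labelled neutral.
#' @param phylo_signal in \[0, 1\]: trait weight in the phylogenetic
#'   coordinates.
#' @param missing_fraction in \[0, 1): fraction of (pair, environment)
#'   cells dropped uniformly at random.
#' @param seed integer seed; identical config + seed gives identical
#'   output.
#' @return list of class `"microkge_synth_config"`.
#' @export
synthetic_config <- function(n_strains = 20L, n_environments = 40L,
                             trait_dim = 4L, env_groups = 8L,
                             noise_sd = 0.3, neutral_band = 0.25,
                             phylo_signal = 0.8, missing_fraction = 0.01,
                             seed = 1L) {
  num1 <- function(x, nm) {
    check_that(is.numeric(x) && length(x) == 1 && is.finite(x),
               paste0(nm, " must be a single finite number"))
  }
  for (nm in c("n_strains", "n_environments", "trait_dim", "env_groups",
               "noise_sd", "neutral_band", "phylo_signal",
               "missing_fraction", "seed")) {
    num1(get(nm), nm)
  }
  check_that(n_strains >= 2, "n_strains must be >= 2")
  check_that(n_environments >= 1, "n_environments must be >= 1")
  check_that(trait_dim >= 1, "trait_dim must be >= 1")
  check_that(env_groups >= 1 && env_groups <= n_environments,
             "env_groups must be in [1, n_environments]")
  check_that(noise_sd >= 0, "noise_sd must be nonnegative")
  check_that(neutral_band >= 0, "neutral_band must be nonnegative")
  check_that(phylo_signal >= 0 && phylo_signal <= 1,
             "phylo_signal must be in [0, 1]")
  check_that(missing_fraction >= 0 && missing_fraction < 1,
             "missing_fraction must be in [0, 1)")
  structure(list(n_strains = as.integer(n_strains),
                 n_environments = as.integer(n_environments),
                 trait_dim = as.integer(trait_dim),
                 env_groups = as.integer(env_groups),
                 noise_sd = noise_sd, neutral_band = neutral_band,
                 phylo_signal = phylo_signal,
                 missing_fraction = missing_fraction,
                 seed = as.integer(seed)),
            class = "microkge_synth_config")
}

#' Generate a synthetic interaction table and phylogenetic features
#'
#' Produces one record per ordered pair of distinct strains per
#' environment (minus a `missing_fraction` dropped uniformly at random),
#' each carrying both the continuous effect and its discretized label
#' under `neutral_band`, plus a strain x `trait_dim` phylogenetic feature
#' matrix. See [synthetic_config()] for the generative model.
#'
#' @param config a [synthetic_config()].
#' @return list with `records` (data.frame: sender, receiver, environment,
#'   effect, label), `phylo` (data.frame: strain_id, f1..f_m),
#'   `environment_groups` (named integer vector: archetype per
#'   environment) and `config`.
#' @export
generate_dataset <- function(config = synthetic_config()) {
  check_that(inherits(config, "microkge_synth_config"),
             "config must come from synthetic_config()")
  set.seed(config$seed)
  ns <- config$n_strains; ne <- config$n_environments
  m <- config$trait_dim
  strains <- sprintf("S%02d", seq_len(ns))
  envs <- sprintf("env%02d", seq_len(ne))
  group <- rep_len(seq_len(config$env_groups), ne)
  names(group) <- envs

  traits <- matrix(stats::rnorm(ns * m), ns, m, dimnames = list(strains))
  mixers <- lapply(seq_len(config$env_groups), function(g) {
    matrix(stats::rnorm(m * m), m, m)
  })
  # pair-level bilinear signal per archetype, scaled to unit-order variance
  signal <- lapply(mixers, function(M) traits %*% M %*% t(traits) / m)

  off_diag <- which(row(diag(ns)) != col(diag(ns)))  # ordered pairs
  sender_i <- row(diag(ns))[off_diag]
  receiver_i <- col(diag(ns))[off_diag]
  n_pairs <- length(off_diag)

  records <- do.call(rbind, lapply(seq_len(ne), function(e) {
    eff <- signal[[group[e]]][off_diag]
    data.frame(sender = strains[sender_i], receiver = strains[receiver_i],
               environment = envs[e], effect = eff,
               stringsAsFactors = FALSE)
  }))
  if (config$noise_sd > 0) {
    records$effect <- records$effect +
      stats::rnorm(nrow(records), sd = config$noise_sd)
  }
  records$label <- discretize_effect(records$effect, config$neutral_band)
  if (config$missing_fraction > 0) {
    keep <- stats::runif(nrow(records)) >= config$missing_fraction
    records <- records[keep, , drop = FALSE]
  }
  rownames(records) <- NULL

  noise <- matrix(stats::rnorm(ns * m), ns, m)
  coords <- config$phylo_signal * traits + (1 - config$phylo_signal) * noise
  phylo <- data.frame(strain_id = strains, coords, stringsAsFactors = FALSE)
  names(phylo) <- c("strain_id", paste0("f", seq_len(m)))
  rownames(phylo) <- NULL

  list(records = records, phylo = phylo, environment_groups = group,
       config = config)
}
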