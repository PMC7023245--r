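# Synthetic ProTherm-like datasets with known ground truth.
#
# Generative model (chosen as the minimal structure that makes every
# downstream stage testable and falsifiable):
#   * each substitution type s gets a mean effect mu_s = +/- effect_mean,
#     positive with probability `stability_bias`, and within-type spread
#     effect_sd (one substitution type really does show a wide range of
#     energy changes across proteins and conditions);
#   * each protein carries a Normal(0, protein_effect_sd) offset;
#   * a single record:  ddg = mu_s + offset + N(0, effect_sd)
#                             + N(0, measurement_noise_sd);
#   * a double record sums two independent single-substitution draws, adds
#     the protein offset, an epistasis term N(0, epistasis_sd) and
#     measurement noise.

#' Configuration of the synthetic-data generator
#'
#' @param n_substitution_types distinct substitution keys drawn (<= 380).
#' @param effect_mean per-type mean effect magnitude |mu_s| (kcal/mol).
#' @param effect_sd within-type spread sigma_s (kcal/mol).
#' @param n_proteins number of synthetic proteins.
#' @param n_single_records,n_double_records record counts to emit.
#' @param protein_effect_sd sd of per-protein offsets (kcal/mol).
#' @param measurement_noise_sd experimental noise sd (kcal/mol).
#' @param epistasis_sd sd of the non-additive term for doubles (kcal/mol).
#' @param stability_bias probability that a type's mean is positive
#'   (stabilizing); 0.8 qualitatively reproduces datasets where the sampler
#'   over-predicts stability.
#' @param seed integer RNG seed; one RNG stream per generate call.
#' @return a validated `synthetic_config` list.
#' @export
synthetic_config <- function(n_substitution_types = 30L,
                             effect_mean = 1.5,
                             effect_sd = 0.5,
                             n_proteins = 10L,
                             n_single_records = 400L,
                             n_double_records = 0L,
                             protein_effect_sd = 0.3,
                             measurement_noise_sd = 0.3,
                             epistasis_sd = 0.25,
                             stability_bias = 0.5,
                             seed = 1L) {
  cfg <- list(n_substitution_types = as.integer(n_substitution_types),
              effect_mean = effect_mean, effect_sd = effect_sd,
              n_proteins = as.integer(n_proteins),
              n_single_records = as.integer(n_single_records),
              n_double_records = as.integer(n_double_records),
              protein_effect_sd = protein_effect_sd,
              measurement_noise_sd = measurement_noise_sd,
              epistasis_sd = epistasis_sd,
              stability_bias = stability_bias,
              seed = as.integer(seed))
  if (cfg$n_substitution_types < 1L || cfg$n_substitution_types > 380L) {
    stop("n_substitution_types must be in 1..380", call. = FALSE)
  }
  sds <- c(cfg$effect_sd, cfg$protein_effect_sd, cfg$measurement_noise_sd,
           cfg$epistasis_sd)
  if (any(sds < 0)) stop("standard deviations must be >= 0", call. = FALSE)
  if (cfg$n_single_records < 0L || cfg$n_double_records < 0L ||
      cfg$n_proteins < 1L) {
    stop("counts must be non-negative (>= 1 protein)", call. = FALSE)
  }
  if (cfg$stability_bias < 0 || cfg$stability_bias > 1) {
    stop("stability_bias must lie in [0, 1]", call. = FALSE)
  }
  structure(cfg, class = "synthetic_config")
}

split_key <- function(key) strsplit(key, ">", fixed = TRUE)[[1]]

# One mutation-string for key(s) at distinct uniform positions in 1..300.
make_mutation_string <- function(keys) {
  pos <- sample.int(300L, length(keys), replace = FALSE)
  paste(vapply(seq_along(keys), function(j) {
    wm <- split_key(keys[j])
    paste0(wm[1], pos[j], wm[2])
  }, character(1)), collapse = "+")
}

#' Generate a synthetic mutation dataset with ground truth
#'
#' Identical seeds give bit-identical output. Positions are uniform in
#' 1..300; substitution keys and proteins are drawn uniformly per record.
#'
#' @param cfg a [synthetic_config()].
#' @return list with elements `dataset` (a `ddg_dataset`) and `truth`
#'   (`ddg_ground_truth`: per-key `(mu, sigma)`, per-protein offsets, a
#'   per-record table of noiseless components, and the config echo).
#' @export
generate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  with_seed(cfg$seed, {
    keys <- sample(all_substitution_keys(), cfg$n_substitution_types)
    sign_s <- ifelse(stats::runif(cfg$n_substitution_types) <
                       cfg$stability_bias, 1, -1)
    mu <- sign_s * cfg$effect_mean
    names(mu) <- keys
    proteins <- sprintf("P%03d", seq_len(cfg$n_proteins))
    offsets <- stats::rnorm(cfg$n_proteins, 0, cfg$protein_effect_sd)
    names(offsets) <- proteins

    n_total <- cfg$n_single_records + cfg$n_double_records
    rec <- vector("list", n_total)
    truth_rows <- vector("list", n_total)
    for (i in seq_len(n_total)) {
      is_double <- i > cfg$n_single_records
      k <- sample(keys, if (is_double) 2L else 1L, replace = FALSE)
      p <- sample(proteins, 1L)
      sub_effects <- mu[k] + stats::rnorm(length(k), 0, cfg$effect_sd)
      epi <- if (is_double) stats::rnorm(1, 0, cfg$epistasis_sd) else 0
      noiseless <- sum(sub_effects) + offsets[[p]] + epi
      obs <- noiseless + stats::rnorm(1, 0, cfg$measurement_noise_sd)
      id <- sprintf("R%05d", i)
      rec[[i]] <- data.frame(record_id = id, protein_id = p,
                             mutation = make_mutation_string(k),
                             ddg = obs, stringsAsFactors = FALSE)
      truth_rows[[i]] <- data.frame(
        record_id = id, keys = paste(k, collapse = "|"),
        sub_effect_sum = sum(sub_effects), protein_offset = offsets[[p]],
        epistasis = epi, noiseless = noiseless, stringsAsFactors = FALSE)
    }
    records <- do.call(rbind, rec) %||%
      data.frame(record_id = character(), protein_id = character(),
                 mutation = character(), ddg = numeric())
    kind <- if (cfg$n_double_records == 0L) "single"
            else if (cfg$n_single_records == 0L) "double" else "mixed"
    dataset <- ddg_dataset(records, kind = kind,
                           provenance = sprintf("synthetic(seed=%d)",
                                                cfg$seed))
    truth <- structure(list(
      mu = mu, sigma = stats::setNames(rep(cfg$effect_sd, length(keys)),
                                       keys),
      protein_offsets = offsets,
      records = do.call(rbind, truth_rows),
      config = unclass(cfg)), class = "ddg_ground_truth")
    list(dataset = dataset, truth = truth)
  })
}

#' Ground-truth marginal CDF of observed ddG for one substitution type
#'
#' The marginal distribution of a single-mutation record of type `key`,
#' pooled over proteins: Gaussian with the type's mean and the within-type,
#' protein and measurement variances combined in quadrature. This is the
#' oracle against which learned empirical CDFs are scored.
#'
#' @param gt a `ddg_ground_truth`.
#' @param key substitution key, e.g. `"A>S"`.
#' @param x numeric evaluation point(s), kcal/mol.
#' @return probabilities.
#' @export
true_cdf <- function(gt, key, x) {
  stopifnot(inherits(gt, "ddg_ground_truth"))
  if (!key %in% names(gt$mu)) stop("unknown key ", sQuote(key), call. = FALSE)
  total_sd <- sqrt(gt$sigma[[key]]^2 + gt$config$protein_effect_sd^2 +
                     gt$config$measurement_noise_sd^2)
  stats::pnorm(x, mean = gt$mu[[key]], sd = total_sd)
}

#' Write ground truth to a JSON file
#' @param gt a `ddg_ground_truth`.
#' @param path output path.
#' @export
write_ground_truth <- function(gt, path) {
  jsonlite::write_json(list(mu = as.list(gt$mu), sigma = as.list(gt$sigma),
                            protein_offsets = as.list(gt$protein_offsets),
                            records = gt$records, config = gt$config),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
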