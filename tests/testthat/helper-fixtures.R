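# Shared fixtures and naive oracles. Everything is generated in code; the
# suite ships no data files.

options(ddgsampler.quiet = TRUE)

# A small hand-written dataset frame.
tiny_records <- function() {
  data.frame(
    record_id = c("r1", "r2", "r3", "r4", "r5", "r6"),
    protein_id = c("1ABC", "1ABC", "2XYZ", "2XYZ", "1ABC", "2XYZ"),
    mutation = c("A23S", "A101S", "F45L", "A23S+F45L", "F45L", "A23S"),
    ddg = c(1.0, 2.0, 0.5, -1.2, 0.7, 1.4),
    stringsAsFactors = FALSE)
}

tiny_dataset <- function() ddg_dataset(tiny_records())

# Random valid dataset for round-trip property tests.
random_dataset <- function(n, seed) {
  with_seed_test(seed, {
    keys <- sample(all_substitution_keys(), min(20, 380))
    rows <- lapply(seq_len(n), function(i) {
      n_ev <- sample(1:2, 1)
      k <- sample(keys, n_ev)
      pos <- sample.int(999, n_ev)
      mut <- paste(mapply(function(kk, pp) {
        wm <- strsplit(kk, ">", fixed = TRUE)[[1]]
        paste0(wm[1], pp, wm[2])
      }, k, pos), collapse = "+")
      data.frame(record_id = sprintf("rec%04d", i),
                 protein_id = sample(c("1ABC", "2DEF", "3GHI"), 1),
                 mutation = mut,
                 ddg = round(stats::rnorm(1, 0, 2), 6),
                 stringsAsFactors = FALSE)
    })
    ddg_dataset(do.call(rbind, rows))
  })
}

# Seed scope helper for tests (mirrors the package-internal one).
with_seed_test <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

# Naive Eq.-style sign-accuracy loop (independent oracle).
naive_sign_accuracy <- function(pred, obs) {
  hits <- 0L
  for (k in seq_along(pred)) {
    s_pred <- if (pred[k] >= 0) 1 else -1
    s_obs <- if (obs[k] >= 0) 1 else -1
    if (s_pred == s_obs) hits <- hits + 1L
  }
  hits / length(pred)
}

# Naive rejection sampler from a step ECDF: propose a distinct support value
# uniformly, accept proportionally to its probability mass.
rejection_sample_ecdf <- function(ec, n_draws) {
  support <- unique(ec$values)
  mass <- tabulate(match(ec$values, support), length(support)) / ec$n
  max_mass <- max(mass)
  out <- numeric(0)
  while (length(out) < n_draws) {
    cand <- sample(support, 1)
    if (stats::runif(1) < mass[match(cand, support)] / max_mass) {
      out <- c(out, cand)
    }
  }
  out
}

# Brute-force per-key value collection (oracle for learn_substitution_cdfs).
naive_group_by_key <- function(d, indices, min_count) {
  acc <- list()
  for (i in indices) {
    for (ev in parse_mutation_string(d$records$mutation[i])) {
      key <- substitution_key(ev)
      acc[[key]] <- c(acc[[key]], d$records$ddg[i])
    }
  }
  acc[vapply(acc, length, integer(1)) >= min_count]
}

# Kolmogorov distance between a ddg_ecdf and a reference CDF function.
ks_distance <- function(ec, ref_fun) {
  x <- ec$values
  upper <- ecdf_eval(ec, x)
  lower <- c(0, upper[-length(upper)])
  max(pmax(abs(upper - ref_fun(x)), abs(lower - ref_fun(x))))
}
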