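#' Default module-specific emotion profiles
#'
#' Real label selections concentrate on a handful of dominant emotions: in
#' surveys of this kind roughly six labels (worries, shame, anxiety, contempt,
#' joy, calmness) are each provided by at least half of the participants while
#' the remaining labels fall below that bar. The default profiles emulate
#' this: a six-label dominant core carries `core_share` of every module's
#' probability mass, with each module tilting the core towards its own two
#' signature emotions (shame/anxiety, worries/contempt, joy/calmness,
#' contempt/worries for the four default modules); the remaining mass is
#' spread uniformly over the other labels, which consequently fail a 50%
#' participation filter.
#'
#' @param n_modules Number of modules.
#' @param labels The emotion label list.
#' @param core_share Probability mass on the six dominant labels. Default
#'   0.75.
#' @return A `n_modules x length(labels)` probability matrix (rows sum to 1).
#' @export
default_emotion_profiles <- function(n_modules = 4, labels = panas_labels(),
                                     core_share = 0.75) {
  core <- intersect(
    c("worries", "shame", "anxiety", "contempt", "joy", "calmness"), labels
  )
  if (length(core) < 2) core <- labels[seq_len(min(6, length(labels)))]
  tilts <- list(
    c("shame", "anxiety"),
    c("worries", "contempt"),
    c("joy", "calmness"),
    c("contempt", "worries")
  )
  rest <- setdiff(labels, core)
  prof <- matrix(0, n_modules, length(labels),
                 dimnames = list(NULL, labels))
  for (m in seq_len(n_modules)) {
    tilt <- intersect(tilts[[((m - 1) %% 4) + 1]], core)
    if (length(tilt) == 0) tilt <- core[1:2]
    base <- setdiff(core, tilt)
    # tilted labels carry twice the weight of the other core labels
    unit <- core_share / (2 * length(tilt) + length(base))
    prof[m, base] <- unit
    prof[m, tilt] <- 2 * unit
    if (length(rest)) prof[m, rest] <- (1 - core_share) / length(rest)
  }
  prof / rowSums(prof)
}

#' Default module-to-category sampling weights
#'
#' Baseline category popularity follows the observed survey response counts
#' over 4 substances, 10 behaviors and the `"other"` option; coupling between
#' the planted module and the problem type is introduced by multiplying the
#' substance-category odds by `coupling` for the first half of the modules and
#' by `1 / coupling` for the rest (so some modules lean substance, some lean
#' behavior).
#'
#' @param n_modules Number of modules.
#' @param coupling Odds multiplier (>= 1); 1 removes the module-category
#'   association. Default 3.
#' @param categories Category/type map, see [default_categories()].
#' @return A `n_modules x nrow(categories)` probability matrix (rows sum
#'   to 1), columns named by category.
#' @export
default_category_weights <- function(n_modules = 4, coupling = 3,
                                     categories = default_categories()) {
  base_counts <- c(
    alcohol = 66, tobacco = 87, cannabis = 22, other_substance = 11,
    social_media = 85, internet = 65, tv_series = 25, eating = 73, work = 39,
    pornography = 33, shopping = 19, gaming = 38, sex = 17, gambling = 5,
    other = 76
  )
  stopifnot(all(categories$category %in% names(base_counts)))
  base <- base_counts[categories$category] / sum(base_counts[categories$category])
  W <- matrix(0, n_modules, length(base),
              dimnames = list(NULL, categories$category))
  lean_substance <- seq_len(n_modules) <= ceiling(n_modules / 2)
  for (m in seq_len(n_modules)) {
    w <- base
    mult <- if (lean_substance[m]) coupling else 1 / coupling
    w[categories$type == "substance"] <- w[categories$type == "substance"] * mult
    W[m, ] <- w / sum(w)
  }
  W
}

#' Configuration of the synthetic free-association generator
#'
#' Defaults mirror the dimensions of a typical mid-sized survey of this kind:
#' 546 participants, four latent modules with population shares
#' 35/21/29/15%, 77 tokens split 26/19/17/15 over the modules, a within-
#' participant concentration of 0.9 (each association comes from the home
#' module with probability 0.9, otherwise from a uniformly chosen other
#' module), Zipf(1) token popularity inside modules, module-specific emotion
#' profiles and substance/behavior weights, and per-module probabilities of
#' answering "Totally agree" on the intensity item.
#'
#' @param n_participants Number of participants. Default 546.
#' @param n_modules Number of planted modules. Default 4.
#' @param module_weights Home-module population shares. Default
#'   `c(0.35, 0.21, 0.29, 0.15)`.
#' @param tokens_per_module Vocabulary sizes. Default `c(26, 19, 17, 15)`.
#' @param concentration Probability pi that an association is drawn from the
#'   home module; must be at least the uniform baseline `1 / n_modules` and at
#'   most 1. Default 0.9.
#' @param zipf_exponent Token popularity exponent within a module (0 =
#'   uniform). Default 1.
#' @param labels Emotion label list.
#' @param emotion_profiles `n_modules x length(labels)` probability matrix.
#' @param categories Category/type map.
#' @param category_weights `n_modules x nrow(categories)` probability matrix.
#' @param intensity_high Per-module probability of "Totally agree" (intensity
#'   4). Default `c(0.66, 0.74, 0.60, 0.60)`.
#' @param intensity_low_split Conditional distribution of intensities 1-3
#'   given not "Totally agree". Default proportional to `c(3, 3, 25.8)`.
#' @param seed Default seed used by [generate_corpus()].
#' @return A validated `coop_synth_config` list.
#' @export
synthetic_config <- function(n_participants = 546,
                             n_modules = 4,
                             module_weights = c(0.35, 0.21, 0.29, 0.15),
                             tokens_per_module = c(26, 19, 17, 15),
                             concentration = 0.9,
                             zipf_exponent = 1,
                             labels = panas_labels(),
                             emotion_profiles = default_emotion_profiles(n_modules, labels),
                             categories = default_categories(),
                             category_weights = default_category_weights(n_modules, 3, categories),
                             intensity_high = c(0.66, 0.74, 0.60, 0.60),
                             intensity_low_split = c(3, 3, 25.8) / 31.8,
                             seed = 1L) {
  if (length(module_weights) != n_modules || any(module_weights <= 0)) {
    abort("`module_weights` must be positive and of length `n_modules`.",
          class = "coop_config_error")
  }
  if (length(tokens_per_module) != n_modules || any(tokens_per_module < 1)) {
    abort("`tokens_per_module` must be positive and of length `n_modules`.",
          class = "coop_config_error")
  }
  if (concentration < 1 / n_modules - 1e-12 || concentration > 1) {
    abort("`concentration` must lie in [1/n_modules, 1].", class = "coop_config_error")
  }
  if (concentration == 1 && min(tokens_per_module) < 5) {
    abort("With concentration 1 every module vocabulary needs >= 5 tokens.",
          class = "coop_config_error")
  }
  if (sum(tokens_per_module) < 5) {
    abort("Vocabulary too small to draw 5 distinct tokens.", class = "coop_config_error")
  }
  stopifnot(
    nrow(emotion_profiles) == n_modules,
    ncol(emotion_profiles) == length(labels),
    nrow(category_weights) == n_modules,
    ncol(category_weights) == nrow(categories),
    length(intensity_high) == n_modules,
    all(intensity_high >= 0 & intensity_high <= 1),
    length(intensity_low_split) == 3
  )
  structure(
    list(
      n_participants = as.integer(n_participants),
      n_modules = as.integer(n_modules),
      module_weights = module_weights / sum(module_weights),
      tokens_per_module = as.integer(tokens_per_module),
      concentration = concentration,
      zipf_exponent = zipf_exponent,
      labels = labels,
      emotion_profiles = emotion_profiles / rowSums(emotion_profiles),
      categories = as_tibble(categories),
      category_weights = category_weights / rowSums(category_weights),
      intensity_high = intensity_high,
      intensity_low_split = intensity_low_split / sum(intensity_low_split),
      seed = as.integer(seed)
    ),
    class = "coop_synth_config"
  )
}

#' Generate a synthetic free-association corpus with planted modules
#'
#' Each participant receives a home module; their five distinct associations
#' are drawn token-by-token (home module with probability `concentration`,
#' otherwise a uniformly chosen other module; tokens within a module by a
#' Zipf popularity law), each association gets two distinct emotion labels
#' from the *token's* module profile, and the category and intensity item are
#' drawn from the *home* module's models. Fully reproducible from the seed.
#'
#' @param config A [synthetic_config()].
#' @param seed Overrides `config$seed` when given.
#' @return A `coop_simulation`: list with `corpus` (a [coop_corpus]),
#'   `token_modules` (tibble `token`, `module`: the planted token partition),
#'   `participant_modules` (tibble `participant_id`, `module`: planted home
#'   modules) and `config`.
#' @export
generate_corpus <- function(config = synthetic_config(), seed = NULL) {
  stopifnot(inherits(config, "coop_synth_config"))
  seed <- seed %||% config$seed
  nm <- config$n_modules
  vocab <- lapply(seq_len(nm), function(m) {
    sprintf("m%d_t%02d", m, seq_len(config$tokens_per_module[m]))
  })
  zipfw <- lapply(config$tokens_per_module, function(k) {
    w <- seq_len(k)^(-config$zipf_exponent)
    w / sum(w)
  })
  n <- config$n_participants
  ids <- sprintf("p%04d", seq_len(n))

  withr::with_seed(seed, {
    home <- sample.int(nm, n, replace = TRUE, prob = config$module_weights)

    draw_tokens <- function(h) {
      sel <- character(0)
      guard <- 0L
      while (length(sel) < 5) {
        guard <- guard + 1L
        if (guard > 10000L) {
          abort("Vocabulary too small to draw 5 distinct tokens.",
                class = "coop_config_error")
        }
        m <- if (nm == 1 || runif(1) < config$concentration) {
          h
        } else {
          others <- setdiff(seq_len(nm), h)
          others[sample.int(length(others), 1)]
        }
        tok <- vocab[[m]][sample.int(length(vocab[[m]]), 1, prob = zipfw[[m]])]
        if (!tok %in% sel) sel <- c(sel, tok)
      }
      sel
    }

    token_mat <- t(vapply(home, draw_tokens, character(5)))
    token_module <- function(tok) as.integer(sub("^m(\\d+)_.*$", "\\1", tok))

    lab1 <- matrix("", n, 5)
    lab2 <- matrix("", n, 5)
    for (i in seq_len(n)) {
      mods <- token_module(token_mat[i, ])
      for (k in 1:5) {
        picked <- sample(config$labels, 2, prob = config$emotion_profiles[mods[k], ])
        lab1[i, k] <- picked[1]
        lab2[i, k] <- picked[2]
      }
    }

    category <- vapply(home, function(h) {
      sample(config$categories$category, 1, prob = config$category_weights[h, ])
    }, character(1))
    high <- runif(n) < config$intensity_high[home]
    intensity <- ifelse(
      high, 4L,
      sample.int(3L, n, replace = TRUE, prob = config$intensity_low_split)
    )

    wide <- tibble(participant_id = ids)
    for (k in 1:5) {
      wide[[paste0("assoc_", k)]] <- token_mat[, k]
      wide[[paste0("emo_", k, "a")]] <- lab1[, k]
      wide[[paste0("emo_", k, "b")]] <- lab2[, k]
    }
    wide$category <- category
    wide$intensity <- intensity

    corpus <- as_corpus(wide, pipeline_config(
      labels = config$labels, categories = config$categories, seed = seed
    ))

    structure(
      list(
        corpus = corpus,
        token_modules = tibble(
          token = unlist(vocab),
          module = rep(seq_len(nm), config$tokens_per_module)
        ),
        participant_modules = tibble(participant_id = ids, module = home),
        config = config
      ),
      class = "coop_simulation"
    )
  })
}

#' @export
print.coop_simulation <- function(x, ...) {
  cat("<coop_simulation>\n")
  cat("  participants:", n_participants(x$corpus), "in",
      x$config$n_modules, "planted modules\n")
  cat("  vocabulary:  ", nrow(x$token_modules), "tokens\n")
  cat("  concentration:", x$config$concentration, "\n")
  invisible(x)
}

#' Score recovery of the planted structure
#'
#' Compares an estimated token partition and/or participant assignment with
#' the simulation's ground truth via the adjusted Rand index (chance-corrected
#' agreement, 1 = identical up to relabeling) plus confusion matrices.
#'
#' @param truth A `coop_simulation` (or a list with `token_modules` /
#'   `participant_modules`).
#' @param partition Optional estimated `coop_partition` over the planted
#'   tokens (tokens absent from the truth raise an error; planted tokens
#'   missing from the partition are ignored, e.g. filtered-out tokens).
#' @param assignments Optional [assign_participants()] output; unassigned
#'   participants are dropped from the comparison.
#' @return A list of class `coop_recovery`: `token_ari`,
#'   `participant_ari`, `token_confusion`, `participant_confusion` (entries
#'   `NULL`/`NA` when the corresponding estimate was not supplied).
#' @export
score_recovery <- function(truth, partition = NULL, assignments = NULL) {
  out <- list(
    token_ari = NA_real_, participant_ari = NA_real_,
    token_confusion = NULL, participant_confusion = NULL
  )
  if (!is.null(partition)) {
    p <- as_tibble(partition)
    unknown <- setdiff(p$token, truth$token_modules$token)
    if (length(unknown)) {
      abort(paste0("Partition tokens absent from the truth: ",
                   paste(head(unknown, 5), collapse = ", ")),
            class = "coop_consistency_error")
    }
    joined <- inner_join(p, truth$token_modules, by = "token",
                         suffix = c("_est", "_true"))
    out$token_ari <- mclust::adjustedRandIndex(joined$module_est, joined$module_true)
    out$token_confusion <- table(
      planted = joined$module_true, estimated = joined$module_est
    )
  }
  if (!is.null(assignments)) {
    joined <- assignments %>%
      filter(!is.na(.data$module)) %>%
      inner_join(truth$participant_modules, by = "participant_id",
                 suffix = c("_est", "_true"))
    out$participant_ari <- mclust::adjustedRandIndex(
      joined$module_est, joined$module_true
    )
    out$participant_confusion <- table(
      planted = joined$module_true, estimated = joined$module_est
    )
  }
  structure(out, class = "coop_recovery")
}

#' @export
print.coop_recovery <- function(x, ...) {
  cat("<coop_recovery>\n")
  if (!is.na(x$token_ari)) cat("  token ARI:      ", round(x$token_ari, 4), "\n")
  if (!is.na(x$participant_ari)) {
    cat("  participant ARI:", round(x$participant_ari, 4), "\n")
  }
  invisible(x)
}
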