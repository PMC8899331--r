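#' Configuration for a synthetic clustered embedding space
#'
#' @param n_subcategories number of planted sub-categories (>= 2).
#' @param items_per_subcategory items per sub-category.
#' @param dim vector dimensionality (>= 2; must be >= `n_subcategories` so
#'   that mutually separated unit centers exist).
#' @param center_separation in `(0, 1]`: 1 places the cluster centers on
#'   mutually orthogonal axes; smaller values shrink all centers toward a
#'   shared direction (smaller angular spread).
#' @param within_noise per-coordinate Gaussian sd added to the center before
#'   re-normalization (> 0).
#' @param seed RNG seed.
#' @return a `space_config` list.
#' @export
space_config <- function(n_subcategories = 8L, items_per_subcategory = 28L,
                         dim = 50L, center_separation = 1,
                         within_noise = 0.15, seed = 0L) {
  stopifnot(n_subcategories >= 2L, dim >= 2L, items_per_subcategory >= 1L,
            within_noise > 0, center_separation > 0, center_separation <= 1)
  structure(list(n_subcategories = as.integer(n_subcategories),
                 items_per_subcategory = as.integer(items_per_subcategory),
                 dim = as.integer(dim),
                 center_separation = center_separation,
                 within_noise = within_noise, seed = as.integer(seed)),
            class = "space_config")
}

#' Generate a clustered word-vector space with known sub-categories
#'
#' Cluster centers are orthonormal unit vectors (via QR of a Gaussian
#' matrix), optionally pulled toward a common direction by
#' `center_separation < 1`. Item vectors are center + isotropic Gaussian
#' noise, re-normalized to unit length. Item names are synthetic
#' (`"sc3_item07"`). Deterministic under the config seed.
#'
#' @param cfg a [space_config].
#' @return list with `vectors` (a [word_vector_set]) and `labeling` (the
#'   planted [subcategory_labeling], labels `"sc1"...`).
#' @export
generate_embedding_space <- function(cfg) {
  stopifnot(inherits(cfg, "space_config"))
  k <- cfg$n_subcategories; d <- cfg$dim
  if (k > d)
    stop("cannot place ", k, " separated unit centers in ", d,
         " dimensions; increase dim or reduce n_subcategories")
  set.seed(cfg$seed)
  Q <- qr.Q(qr(matrix(stats::rnorm(d * k), d, k)))   # orthonormal centers
  if (cfg$center_separation < 1) {
    u <- stats::rnorm(d); u <- u / sqrt(sum(u^2))
    a <- cfg$center_separation
    Q <- a * Q + (1 - a) * u
    Q <- sweep(Q, 2L, sqrt(colSums(Q^2)), `/`)
  }
  items <- character(0); labels <- character(0)
  vecs <- matrix(0, k * cfg$items_per_subcategory, d)
  row <- 0L
  for (s in seq_len(k)) {
    for (j in seq_len(cfg$items_per_subcategory)) {
      row <- row + 1L
      v <- Q[, s] + stats::rnorm(d, sd = cfg$within_noise)
      vecs[row, ] <- v / sqrt(sum(v^2))
      items[row] <- sprintf("sc%d_item%02d", s, j)
      labels[row] <- paste0("sc", s)
    }
  }
  list(vectors = word_vector_set(items, vecs),
       labeling = subcategory_labeling(items, labels, source = "manual"))
}

#' Configuration for a simulated fluency cohort
#'
#' Per diagnostic group: participant count, word-count distribution, the
#' Markov movement parameters and the age distribution. `p_stay` is the
#' probability of producing the next item inside the current sub-category;
#' on a switch, `p_new_given_switch` is the probability of targeting a
#' not-yet-visited sub-category when one exists (otherwise the switch is a
#' return to a previously visited sub-category).
#'
#' @param groups named list (names exactly `healthy`, `aMCI`, `AD`), each a
#'   list with `n_participants`, `word_count_mean`, `word_count_sd`,
#'   `p_stay`, `p_new_given_switch`, `age_mean`, `age_sd`.
#' @param seed RNG seed.
#' @return a `cohort_config` list.
#' @export
cohort_config <- function(groups, seed = 0L) {
  need <- fluency_groups()
  if (!setequal(names(groups), need))
    stop("groups must be named exactly: ", paste(need, collapse = ", "))
  fields <- c("n_participants", "word_count_mean", "word_count_sd",
              "p_stay", "p_new_given_switch", "age_mean", "age_sd")
  for (g in need) {
    missf <- setdiff(fields, names(groups[[g]]))
    if (length(missf) > 0L)
      stop("group ", g, " config lacks: ", paste(missf, collapse = ", "))
    p <- groups[[g]]
    if (p$p_stay < 0 || p$p_stay > 1 ||
        p$p_new_given_switch < 0 || p$p_new_given_switch > 1)
      stop("probabilities must be in [0, 1] (group ", g, ")")
  }
  structure(list(groups = groups[need], seed = as.integer(seed)),
            class = "cohort_config")
}

#' Simulate fluency transcripts by a Markov walk over sub-categories
#'
#' Each participant's word count is `round(Normal(mean, sd))` truncated at
#' 1. The first item comes from a uniformly chosen sub-category. Each later
#' step stays in the current sub-category with `p_stay` (if an unused item
#' remains there, else a switch is forced and logged); a switch targets an
#' unvisited sub-category with `p_new_given_switch` when one exists and a
#' previously visited one (uniform, excluding the current) otherwise.
#' Items are drawn uniformly without replacement within the target
#' sub-category (`allow_replacement = TRUE` re-uses items, permitting
#' perseverations). Deterministic under the config seed.
#'
#' @param cfg a [cohort_config].
#' @param labeling a [subcategory_labeling] defining the item pool.
#' @param allow_replacement fall back to drawing with replacement.
#' @return list of [fluency_record]; attribute `forced_switches` counts
#'   forced-switch events.
#' @export
generate_cohort <- function(cfg, labeling, allow_replacement = FALSE) {
  stopifnot(inherits(cfg, "cohort_config"),
            inherits(labeling, "subcategory_labeling"))
  pool <- split(names(labeling$mapping), unname(labeling$mapping))
  n_total_items <- length(labeling$mapping)
  set.seed(cfg$seed)
  forced <- 0L
  records <- list()
  idx <- 0L
  for (g in fluency_groups()) {
    p <- cfg$groups[[g]]
    for (i in seq_len(p$n_participants)) {
      idx <- idx + 1L
      n <- max(1L, as.integer(round(stats::rnorm(1, p$word_count_mean,
                                                 p$word_count_sd))))
      if (n > n_total_items && !allow_replacement)
        stop("requested ", n, " words but the labeling has only ",
             n_total_items, " items; set allow_replacement = TRUE")
      used <- lapply(pool, function(x) logical(length(x)))
      remaining <- vapply(pool, length, 1L)
      draw <- function(sc) {
        avail <- which(!used[[sc]])
        pick <- if (allow_replacement && length(avail) == 0L)
          sample.int(length(pool[[sc]]), 1L)
        else avail[sample.int(length(avail), 1L)]
        used[[sc]][pick] <<- TRUE
        remaining[sc] <<- sum(!used[[sc]])
        pool[[sc]][pick]
      }
      scs <- names(pool)
      current <- scs[sample.int(length(scs), 1L)]
      visited <- current
      items <- character(n)
      items[1] <- draw(current)
      if (n > 1L) for (t in 2:n) {
        can_stay <- remaining[current] > 0L || allow_replacement
        stay <- can_stay && stats::runif(1) < p$p_stay
        if (!can_stay) forced <- forced + 1L
        if (!stay) {
          open <- if (allow_replacement) scs else scs[remaining[scs] > 0L]
          unvis <- setdiff(open, visited)
          revis <- setdiff(intersect(open, visited), current)
          target <- if (length(unvis) > 0L && length(revis) > 0L) {
            if (stats::runif(1) < p$p_new_given_switch)
              unvis[sample.int(length(unvis), 1L)]
            else revis[sample.int(length(revis), 1L)]
          } else if (length(unvis) > 0L) unvis[sample.int(length(unvis), 1L)]
          else if (length(revis) > 0L) revis[sample.int(length(revis), 1L)]
          else current  # nothing else open: forced stay
          if (identical(target, current) && !can_stay)
            stop("item pool exhausted; set allow_replacement = TRUE")
          current <- target
          visited <- union(visited, current)
        }
        items[t] <- draw(current)
      }
      records[[idx]] <- fluency_record(
        sprintf("%s_%03d", g, i), g,
        stats::rnorm(1, p$age_mean, p$age_sd), items)
    }
  }
  attr(records, "forced_switches") <- forced
  records
}

#' Default study-shaped simulation scenario
#'
#' A full synthetic stand-in for the study design this package targets:
#' a 224-item space (8 sub-categories x 28 items, 50-d vectors, strong
#' separation) and a cohort of 42 healthy / 24 aMCI / 18 AD participants.
#' Group movement parameters are preset (calibrated once by chain
#' simulation) so that mean returns land near the reported group means
#' (healthy ~ 5.98, aMCI ~ 5.04, AD ~ 2.17), ages match the reported group
#' means/sds, and the orderings AD < aMCI < healthy hold for words,
#' switches and returns. Word-count means (22/17/12) are package defaults,
#' not reported values.
#'
#' @param seed integer seed driving both the space and the cohort.
#' @return list with `space_cfg`, `cohort_cfg`, `space` (vectors +
#'   planted labeling), `labeling`, `records`.
#' @export
default_paper_like_scenario <- function(seed = 0L) {
  seed <- as.integer(seed)
  space_cfg <- space_config(n_subcategories = 8L, items_per_subcategory = 28L,
                            dim = 50L, center_separation = 1,
                            within_noise = 0.15, seed = seed)
  cohort_cfg <- cohort_config(default_group_parameters(), seed = seed + 1L)
  space <- generate_embedding_space(space_cfg)
  records <- generate_cohort(cohort_cfg, space$labeling)
  list(space_cfg = space_cfg, cohort_cfg = cohort_cfg, space = space,
       labeling = space$labeling, records = records)
}

#' Default per-group Markov parameters of the study-shaped scenario
#'
#' @param null_model if `TRUE`, every group gets the healthy parameter set
#'   (identical movement and age distributions; only group sizes differ) —
#'   the no-effect world used for type-I-error checks.
#' @return named list suitable for [cohort_config].
#' @export
default_group_parameters <- function(null_model = FALSE) {
  healthy <- list(n_participants = 42L, word_count_mean = 22,
                  word_count_sd = 6, p_stay = 0.50,
                  p_new_given_switch = 0.35, age_mean = 74.38, age_sd = 7.32)
  if (null_model) {
    amci <- healthy; amci$n_participants <- 24L
    ad <- healthy; ad$n_participants <- 18L
    return(list(healthy = healthy, aMCI = amci, AD = ad))
  }
  list(
    healthy = healthy,
    aMCI = list(n_participants = 24L, word_count_mean = 17,
                word_count_sd = 5, p_stay = 0.50,
                p_new_given_switch = 0.32, age_mean = 71.34, age_sd = 6.59),
    AD = list(n_participants = 18L, word_count_mean = 12,
              word_count_sd = 4, p_stay = 0.55,
              p_new_given_switch = 0.45, age_mean = 78.32, age_sd = 4.76))
}
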