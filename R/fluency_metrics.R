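#' Construct a fluency record
#'
#' One participant's ordered production in the timed category-fluency task.
#' Repetitions (perseverations) are retained; correctness is not judged.
#'
#' @param participant_id character scalar.
#' @param group one of `"healthy"`, `"aMCI"`, `"AD"`.
#' @param age age in years.
#' @param items character vector of produced items, in production order
#'   (may be empty).
#' @return object of class `fluency_record`.
#' @export
fluency_record <- function(participant_id, group, age, items) {
  group <- match.arg(group, c("healthy", "aMCI", "AD"))
  structure(list(participant_id = as.character(participant_id),
                 group = group, age = as.numeric(age),
                 items = as.character(items)),
            class = "fluency_record")
}

#' Group factor levels used throughout the package
#' @return `c("healthy", "aMCI", "AD")`
#' @export
fluency_groups <- function() c("healthy", "aMCI", "AD")

#' Read fluency transcripts from long-format CSV
#'
#' Expected columns: `participant_id, group, age, position, item`
#' (1-based `position`; rows may arrive unsorted).
#'
#' @param path CSV file path.
#' @return list of [fluency_record] objects, one per participant, in first-
#'   appearance order.
#' @export
read_transcripts <- function(path) {
  df <- utils::read.csv(path, colClasses = c(
    participant_id = "character", group = "character", age = "numeric",
    position = "integer", item = "character"))
  need <- c("participant_id", "group", "age", "position", "item")
  if (!all(need %in% names(df)))
    stop("transcript CSV must have columns: ", paste(need, collapse = ", "))
  ids <- unique(df$participant_id)
  lapply(ids, function(id) {
    sub <- df[df$participant_id == id, , drop = FALSE]
    sub <- sub[order(sub$position), , drop = FALSE]
    fluency_record(id, sub$group[1], sub$age[1], sub$item)
  })
}

#' Write fluency records to long-format CSV
#'
#' @param records list of [fluency_record].
#' @param path output path.
#' @export
write_transcripts <- function(records, path) {
  rows <- lapply(records, function(r) {
    n <- length(r$items)
    if (n == 0L) return(NULL)
    data.frame(participant_id = r$participant_id, group = r$group,
               age = r$age, position = seq_len(n), item = r$items)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Map a production sequence to sub-category labels
#'
#' @param rec a [fluency_record].
#' @param lab a [subcategory_labeling].
#' @param skip_unlabeled if `FALSE` (default) an item without a label is an
#'   error naming the item and participant; if `TRUE` such items are dropped
#'   with a warning.
#' @param normalize_case normalize item strings before lookup.
#' @return character vector of labels, in production order.
#' @export
label_sequence <- function(rec, lab, skip_unlabeled = FALSE,
                           normalize_case = TRUE) {
  stopifnot(inherits(rec, "fluency_record"),
            inherits(lab, "subcategory_labeling"))
  items <- if (normalize_case) normalize_item(rec$items) else rec$items
  if (length(items) == 0L) return(character(0))
  hit <- items %in% names(lab$mapping)
  if (!all(hit)) {
    missing <- unique(items[!hit])
    if (!skip_unlabeled)
      stop("unlabeled item(s) for participant ", rec$participant_id, ": ",
           paste(missing, collapse = ", "))
    warning("participant ", rec$participant_id, ": skipped ",
            sum(!hit), " unlabeled item occurrence(s)")
    items <- items[hit]
  }
  unname(lab$mapping[items])
}

#' Movement metrics of a labeled production sequence
#'
#' With `runs` the maximal blocks of consecutive identical labels:
#' switches `S = runs - 1`, distinct sub-categories `K`, returns
#' `R = runs - K` (every re-entry run counts, including repeated returns to
#' the same sub-category), so `R = S - (K - 1)`. Adjusted variants are
#' `100 * count / n_words` (percent); raw fractions are also kept. An empty
#' sequence scores all-zero.
#'
#' @param labels character vector of sub-category labels in production order.
#' @return object of class `fluency_metrics`: `n_words`, `n_subcategories`,
#'   `n_switches`, `n_returns`, `adj_switches`, `adj_returns` (percent),
#'   `frac_switches`, `frac_returns`.
#' @export
compute_metrics <- function(labels) {
  labels <- as.character(labels)
  n <- length(labels)
  if (n == 0L) {
    out <- list(n_words = 0L, n_subcategories = 0L, n_switches = 0L,
                n_returns = 0L, adj_switches = 0, adj_returns = 0,
                frac_switches = 0, frac_returns = 0)
    return(structure(out, class = "fluency_metrics"))
  }
  r <- rle(labels)
  runs <- length(r$lengths)
  K <- length(unique(labels))
  S <- runs - 1L
  R <- runs - K
  structure(list(n_words = n, n_subcategories = K, n_switches = S,
                 n_returns = R,
                 adj_switches = 100 * S / n, adj_returns = 100 * R / n,
                 frac_switches = S / n, frac_returns = R / n),
            class = "fluency_metrics")
}

#' @export
print.fluency_metrics <- function(x, ...) {
  cat(sprintf(
    "<fluency_metrics: n = %d, K = %d, switches = %d, returns = %d, adj. S = %.1f%%, adj. R = %.1f%%>\n",
    x$n_words, x$n_subcategories, x$n_switches, x$n_returns,
    x$adj_switches, x$adj_returns))
  invisible(x)
}

#' Visitation profile of a labeled sequence
#'
#' Run-length encodes the sequence and indexes each run by its ordinal
#' within its own sub-category: the first run of a sub-category is visit 1;
#' its k-th run is return k - 1.
#'
#' @param labels character vector of labels in production order.
#' @return data frame of class `visitation_profile` with columns
#'   `label`, `visit` (1-based ordinal within the label), `length` (words in
#'   the run), `is_return` (`visit > 1`), `run` (global run index).
#' @export
visitation_profile <- function(labels) {
  labels <- as.character(labels)
  if (length(labels) == 0L) {
    out <- data.frame(label = character(0), visit = integer(0),
                      length = integer(0), is_return = logical(0),
                      run = integer(0))
    class(out) <- c("visitation_profile", "data.frame")
    return(out)
  }
  r <- rle(labels)
  visit <- stats::ave(seq_along(r$values), r$values, FUN = seq_along)
  out <- data.frame(label = r$values, visit = as.integer(visit),
                    length = r$lengths, is_return = visit > 1L,
                    run = seq_along(r$values))
  class(out) <- c("visitation_profile", "data.frame")
  out
}

#' Per-participant metrics table for a cohort
#'
#' One row per participant: id, group, age, all movement metrics, plus
#' per-sub-category word counts (`count_<label>`) and proportions of the
#' participant's total word count (`prop_<label>`, summing to 1 when
#' `n_words > 0`).
#'
#' @param records list of [fluency_record].
#' @param lab a [subcategory_labeling].
#' @param skip_unlabeled forwarded to [label_sequence].
#' @param collapse_repetitions collapse exact consecutive duplicate items
#'   (perseverations) before labeling; default `FALSE` (all productions are
#'   scored).
#' @return data frame with `group` as a factor over [fluency_groups].
#' @export
cohort_metrics_table <- function(records, lab, skip_unlabeled = FALSE,
                                 collapse_repetitions = FALSE) {
  if (length(records) == 0L) stop("need at least one record")
  lbl_all <- lab$labels
  rows <- lapply(records, function(rec) {
    items <- rec$items
    if (collapse_repetitions && length(items) > 1L)
      items <- items[c(TRUE, items[-1L] != items[-length(items)])]
    rec2 <- rec; rec2$items <- items
    labs <- label_sequence(rec2, lab, skip_unlabeled = skip_unlabeled)
    met <- compute_metrics(labs)
    if (met$n_words == 0L)
      warning("participant ", rec$participant_id,
              " has an empty (or fully skipped) transcript; all-zero row")
    counts <- table(factor(labs, levels = lbl_all))
    props <- if (met$n_words > 0L) as.numeric(counts) / met$n_words
             else rep(0, length(lbl_all))
    cbind(data.frame(participant_id = rec$participant_id, group = rec$group,
                     age = rec$age, n_words = met$n_words,
                     n_subcategories = met$n_subcategories,
                     n_switches = met$n_switches, n_returns = met$n_returns,
                     adj_switches = met$adj_switches,
                     adj_returns = met$adj_returns),
          stats::setNames(as.data.frame(as.list(as.numeric(counts))),
                          paste0("count_", lbl_all)),
          stats::setNames(as.data.frame(as.list(props)),
                          paste0("prop_", lbl_all)))
  })
  out <- do.call(rbind, rows)
  out$group <- factor(out$group, levels = fluency_groups())
  rownames(out) <- NULL
  out
}

#' Group-average visitation profile
#'
#' Mean run length per (sub-category visitation ordinal, group), pooled over
#' all sub-categories: the quantity plotted as "visit 1, return 1, return 2,
#' ..." bar profiles.
#'
#' @param records list of [fluency_record].
#' @param lab a [subcategory_labeling].
#' @param max_visit largest visitation ordinal retained. Default 6.
#' @return data frame: `group`, `visit`, `mean_length`, `n_runs`.
#' @export
group_visitation_summary <- function(records, lab, max_visit = 6L) {
  rows <- lapply(records, function(rec) {
    vp <- visitation_profile(label_sequence(rec, lab))
    if (nrow(vp) == 0L) return(NULL)
    vp$group <- rec$group
    vp
  })
  all <- do.call(rbind, rows)
  if (is.null(all)) stop("no non-empty transcripts")
  all <- all[all$visit <= max_visit, , drop = FALSE]
  agg <- stats::aggregate(length ~ group + visit, data = all, FUN = mean)
  cnt <- stats::aggregate(length ~ group + visit, data = all, FUN = length)
  names(agg)[3] <- "mean_length"
  agg$n_runs <- cnt$length
  agg$group <- factor(agg$group, levels = fluency_groups())
  agg[order(agg$group, agg$visit), , drop = FALSE]
}
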