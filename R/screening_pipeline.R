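# Experiment orchestration: the per-target screening protocol.
#
# Each benchmark dataset groups several targets; each target is a labeled
# train/test split of actives and inactives. The protocol caps every target
# at its first `subset_cap` actives and equally many inactives, learns a
# cost table per target on the train half, averages tables within each
# dataset and then across datasets into one global mean table, and finally
# scores every target's test half against its train half under that mean
# table by nearest-neighbour classification.

#' Cap a target at its first n actives and as many inactives
#'
#' If at least `cap` actives exist, the first `cap` of each class are kept;
#' otherwise all actives and an equal number of leading inactives. Input
#' order (file order) is preserved.
#'
#' @param actives,inactives Lists of `erg_graph` objects in file order.
#' @param cap Positive integer, default 100.
#' @param target Target name used in error messages.
#' @return List with elements `actives` and `inactives`, equal length.
#' @export
subset_target <- function(actives, inactives, cap = 100L, target = "?") {
  stopifnot(cap >= 1L)
  if (length(actives) == 0L)
    stop("target '", target, "' has no active molecules", call. = FALSE)
  k <- min(cap, length(actives))
  if (length(inactives) < k)
    stop(sprintf("target '%s' has %d inactives but %d are needed",
                 target, length(inactives), k), call. = FALSE)
  list(actives = actives[seq_len(k)], inactives = inactives[seq_len(k)])
}

cap_half <- function(graphs, cap, target) {
  cls <- vapply(graphs, function(g) g$class, character(1))
  s <- subset_target(graphs[cls == "active"], graphs[cls == "inactive"],
                     cap, target)
  c(s$actives, s$inactives)
}

#' Experiment configuration
#'
#' @param datasets Named list of benchmark datasets; each element is a list
#'   of [erg_dataset()] targets.
#' @param subset_cap Per-target cap on actives (and matched inactives),
#'   default 100.
#' @param init Initial `cost_table` for learning (default [harper_costs()]).
#' @param max_iter Learning iterations per target, default 50.
#' @param method GED method, `"bipartite"` (default) or `"exact"`.
#' @param per_target_costs Evaluate each target under its own learned table
#'   instead of the global mean (diagnostic mode)? Default `FALSE`.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(datasets, subset_cap = 100L,
                              init = harper_costs(), max_iter = 50L,
                              method = c("bipartite", "exact"),
                              per_target_costs = FALSE) {
  method <- match.arg(method)
  stopifnot(is.list(datasets), length(datasets) >= 1L)
  if (is.null(names(datasets)) || any(names(datasets) == ""))
    stop("datasets must be a named list", call. = FALSE)
  structure(list(datasets = datasets, subset_cap = as.integer(subset_cap),
                 init = init, max_iter = as.integer(max_iter),
                 method = method, per_target_costs = per_target_costs),
            class = "experiment_config")
}

#' Run the full screening experiment
#'
#' Learns edit costs per target, averages within and then across datasets,
#' and evaluates every target's test half against its train half under the
#' resulting mean cost table. Deterministic for a given configuration. A
#' target that fails (e.g. from a degenerate subset) is reported with an
#' `NA` accuracy and its error message, never silently dropped.
#'
#' @param cfg An [experiment_config()].
#' @return An object of class `experiment_report`: list with `per_target`
#'   (data frame `dataset`, `target`, `n_active`, `n_inactive`, `accuracy`,
#'   `error`), `per_dataset_mean` (data frame `dataset`, `accuracy`),
#'   `grand_mean` (unweighted mean over datasets, matching the one-number-
#'   per-dataset reporting convention), `costs` (the mean `cost_table`
#'   used), and `per_dataset_costs`.
#' @export
run_experiment <- function(cfg) {
  stopifnot(inherits(cfg, "experiment_config"))
  ds_tables <- list()
  target_tables <- list()

  # learning pass
  for (ds in names(cfg$datasets)) {
    tabs <- list()
    for (tg in cfg$datasets[[ds]]) {
      key <- paste(ds, tg$name, sep = "/")
      tabs[[tg$name]] <- tryCatch({
        tr <- cap_half(tg$train, cfg$subset_cap, tg$name)
        learn_costs(tr, cfg$init, max_iter = cfg$max_iter,
                    method = cfg$method)$final
      }, error = function(e) e)
      target_tables[[key]] <- tabs[[tg$name]]
    }
    ok <- Filter(function(x) inherits(x, "cost_table"), tabs)
    if (length(ok) > 0L) ds_tables[[ds]] <- mean_costs(unname(ok))
  }
  if (length(ds_tables) == 0L)
    stop("cost learning failed for every dataset", call. = FALSE)
  global <- mean_costs(unname(ds_tables))

  # evaluation pass
  rows <- list()
  for (ds in names(cfg$datasets)) {
    for (tg in cfg$datasets[[ds]]) {
      key <- paste(ds, tg$name, sep = "/")
      eval_costs <- if (cfg$per_target_costs &&
                        inherits(target_tables[[key]], "cost_table"))
        target_tables[[key]] else global
      row <- tryCatch({
        tr <- cap_half(tg$train, cfg$subset_cap, tg$name)
        te <- cap_half(tg$test, cfg$subset_cap, tg$name)
        cls <- vapply(c(tr, te), function(g) g$class, character(1))
        acc <- evaluate_accuracy(te, tr, eval_costs, method = cfg$method)
        data.frame(dataset = ds, target = tg$name,
                   n_active = sum(cls == "active"),
                   n_inactive = sum(cls == "inactive"),
                   accuracy = acc, error = NA_character_,
                   stringsAsFactors = FALSE)
      }, error = function(e)
        data.frame(dataset = ds, target = tg$name, n_active = NA_integer_,
                   n_inactive = NA_integer_, accuracy = NA_real_,
                   error = conditionMessage(e), stringsAsFactors = FALSE))
      rows[[key]] <- row
    }
  }
  per_target <- do.call(rbind, unname(rows))
  ds_mean <- stats::aggregate(accuracy ~ dataset, data = per_target, FUN = mean,
                              na.action = stats::na.omit)
  structure(list(per_target = per_target,
                 per_dataset_mean = ds_mean,
                 grand_mean = mean(ds_mean$accuracy),
                 costs = global,
                 per_dataset_costs = ds_tables),
            class = "experiment_report")
}

#' @export
print.experiment_report <- function(x, ...) {
  cat(sprintf("experiment_report: %d target(s) in %d dataset(s)\n",
              nrow(x$per_target), nrow(x$per_dataset_mean)))
  for (i in seq_len(nrow(x$per_dataset_mean)))
    cat(sprintf("  %-12s %6.2f%%\n", x$per_dataset_mean$dataset[i],
                x$per_dataset_mean$accuracy[i]))
  cat(sprintf("  %-12s %6.2f%%\n", "mean", x$grand_mean))
  invisible(x)
}

#' Export an experiment report as tabular text
#'
#' @param report An `experiment_report`.
#' @param path Output path (tab-separated per-target table; dataset means
#'   appended as comment lines).
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  utils::write.table(report$per_target, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  lines <- c(sprintf("# dataset-mean\t%s\t%.6g", report$per_dataset_mean$dataset,
                     report$per_dataset_mean$accuracy),
             sprintf("# grand-mean\t%.6g", report$grand_mean))
  cat(lines, file = path, sep = "\n", append = TRUE)
  invisible(path)
}
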