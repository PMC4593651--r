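#' Mean star-value histogram over an ensemble
#'
#' Bins every network of an ensemble with the same fixed bins and averages
#' the normalized counts across realizations.
#'
#' @param nets A list of `igraph` networks (e.g. from [null_ensemble()]).
#' @param bins Number of bins on `[0, 1]`.
#' @param denom Directed denominator convention.
#' @return A tibble of class `sv_dist`; `freq` is the across-realization
#'   mean and still sums to 1.
#' @export
ensemble_sv_distribution <- function(nets, bins = 20, denom = "P1") {
  freqs <- vapply(nets, function(g) {
    sv_distribution(star_values(g, denom = denom), bins = bins, quiet = TRUE)$freq
  }, numeric(bins))
  counts <- vapply(nets, function(g) {
    sv_distribution(star_values(g, denom = denom), bins = bins, quiet = TRUE)$count
  }, numeric(bins))
  out <- sv_distribution(0.5, bins = bins, quiet = TRUE)  # template for bin columns
  out$count <- rowMeans(counts)
  out$freq <- rowMeans(freqs)
  out
}

#' Benchmark-style summary table for a set of networks
#'
#' One summary row per network: vertex count, edge counts under both
#' conventions, diameter, characteristic path length, mean clustering
#' coefficient and mean star value, computed on the largest (strong for
#' directed, weak for undirected) component. An entry may be a generator
#' thunk — a `function(seed)` returning a network — in which case the row
#' reports means over `reps` seeded realizations (`seed + 0 ..
#' seed + reps - 1`) and the modal diameter.
#'
#' @param networks Named list of `igraph` networks and/or `function(seed)`
#'   generator thunks.
#' @param reps Realizations per generator entry (default 20).
#' @param seed Base seed for generator entries.
#' @param denom Directed denominator convention.
#' @return A tibble with one row per entry: `network`, `n_reps`, and the
#'   [summarize_network()] columns.
#' @examples
#' run_table1(list(K4 = igraph::make_full_graph(4),
#'                 er = function(seed) generate_er(40, 0.2, seed)), reps = 3)
#' @export
run_table1 <- function(networks, reps = 20, seed = 1, denom = "P1") {
  stopifnot(length(networks) > 0, !is.null(names(networks)))
  purrr::imap_dfr(networks, function(entry, name) {
    row <- tryCatch({
      if (is.function(entry)) {
        rows <- purrr::map_dfr(seq_len(reps) - 1L, function(i) {
          summarize_network(entry(seed + i), denom = denom)
        })
        summarise(rows,
                  n_vertices = mean(.data$n_vertices),
                  n_edges_unique = mean(.data$n_edges_unique),
                  n_edges_arcs = mean(.data$n_edges_arcs),
                  diameter = .modal(.data$diameter),
                  cpl = mean(.data$cpl), mean_cc = mean(.data$mean_cc),
                  mean_sv = mean(.data$mean_sv)) |>
          mutate(n_reps = reps, .before = 1)
      } else {
        summarize_network(entry, denom = denom) |> mutate(n_reps = 1L, .before = 1)
      }
    }, error = function(e) {
      abort(sprintf("run_table1: entry '%s' failed: %s", name, conditionMessage(e)))
    })
    mutate(row, network = name, .before = 1)
  })
}

.modal <- function(x) {
  tab <- sort(table(x), decreasing = TRUE)
  as.numeric(names(tab)[1])
}

# CSV with '# key=value' header comments; deterministic (no timestamps).
.write_report_csv <- function(df, path, header = character(0)) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header) > 0) writeLines(paste0("# ", header), con)
  df <- as.data.frame(df)
  for (j in seq_along(df)) if (is.matrix(df[[j]])) df[[j]] <- as.vector(df[[j]])
  utils::write.table(df, con, sep = ",", row.names = FALSE, quote = FALSE, na = "-")
  invisible(path)
}

#' Full analysis bundle for one attributed network
#'
#' Runs the whole pipeline on one network and writes canonical CSV outputs
#' to a directory: per-vertex star values and their histogram, a one-row
#' topological summary, and — when attributes are supplied — the disparity
#' table/profile, the workload-closure table, and (directed networks only)
#' the brokerage profiles and census. Optional null-model comparisons add a
#' mean star-value histogram per requested model. Every file starts with
#' `# key=value` comment lines recording the configuration and seed, and
#' identical invocations are byte-identical.
#'
#' @param net An `igraph` network.
#' @param attrs Optional [attribute_map()]; required for attribute analyses.
#' @param outdir Output directory (created if needed).
#' @param seed Base seed for null ensembles.
#' @param bins Histogram bins.
#' @param denom Directed denominator convention.
#' @param nulls Character subset of `c("iso", "ms", "bms")`, or `NULL`.
#' @param reps Replicates per null ensemble.
#' @param top_k Top-k length for the brokerage census.
#' @return Invisibly, a named list of the file paths written.
#' @export
run_full_analysis <- function(net, attrs = NULL, outdir, seed = 1, bins = 20,
                              denom = "P1", nulls = NULL, reps = 20, top_k = 10) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  directed <- igraph::is_directed(net)
  hdr <- c(sprintf("directed=%s", directed), sprintf("bins=%d", bins),
           sprintf("denom=%s", denom), sprintf("seed=%d", seed))
  paths <- list()
  p <- function(f) file.path(outdir, f)

  sv <- star_values(net, denom = denom)
  paths$sv <- .write_report_csv(sv, p("sv_vertices.csv"), hdr)
  paths$sv_hist <- .write_report_csv(sv_distribution(sv, bins, quiet = TRUE),
                                     p("sv_histogram.csv"), hdr)
  paths$summary <- .write_report_csv(summarize_network(net, denom = denom),
                                     p("summary.csv"), hdr)

  if (!is.null(attrs)) {
    und <- if (directed) igraph::as_undirected(net, mode = "collapse") else net
    paths$disparity <- .write_report_csv(disparity_table(und, attrs),
                                         p("disparity_vertices.csv"), hdr)
    paths$disparity_profile <- .write_report_csv(disparity_profile(und, attrs),
                                                 p("disparity_profile.csv"), hdr)
    paths$wcc <- .write_report_csv(wcc_table(und, attrs), p("wcc.csv"), hdr)
    if (directed) {
      census <- brokerage_census(net, attrs, k = top_k)
      paths$brokerage <- .write_report_csv(census$profiles,
                                           p("brokerage_profiles.csv"), hdr)
      paths$brokerage_top <- .write_report_csv(census$top, p("brokerage_top.csv"), hdr)
      for (r in names(census$best)) {
        m <- census$best[[r]]
        df <- cbind(data.frame(group = rownames(m)), as.data.frame(m, stringsAsFactors = FALSE))
        paths[[paste0("best_", r)]] <- .write_report_csv(
          df, p(sprintf("brokerage_best_%s.csv", r)),
          c(hdr, paste0("orientation=", attr(census, "orientation"))))
      }
    }
  }

  for (model in nulls %||% character(0)) {
    if (model == "bms" && is.null(attrs)) {
      abort("Null model 'bms' requested but no attributes supplied.")
    }
    nets <- null_ensemble(net, model, attrs = attrs, reps = reps, seed = seed)
    paths[[paste0("null_", model)]] <- .write_report_csv(
      ensemble_sv_distribution(nets, bins = bins, denom = denom),
      p(sprintf("null_%s_sv_histogram.csv", model)),
      c(hdr, sprintf("model=%s", model), sprintf("reps=%d", reps)))
  }
  invisible(paths)
}
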