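#' Assemble a run configuration
#'
#' A run configuration collects input paths and module parameters for
#' [run_pipeline()]. Every parameter defaults to the value used throughout
#' the package (10 s bins, 5-min windows, k = 3, 20 um^2 size filter,
#' 3-dot positivity, expression > 0), so a minimal config only names the
#' inputs. Configs can also be stored as YAML and read back with
#' [read_run_config()]; the effective (fully defaulted) config is echoed
#' into the output directory of every run.
#'
#' @param ephys `NULL` or a list: `spikes`, `protocol` (paths), optional
#'   `vm`, and optional `bin_width_s`, `baseline_window_s`, `drug_window_s`,
#'   `k`.
#' @param image `NULL` or a list: `path`, optional `sidecar`,
#'   `seed_channel`, optional `channels`, `min_size_um2`, `dot_threshold`,
#'   `min_sep_px`, `positive_min_dots`, `reference`, `queries` (list),
#'   `exclude` (path).
#' @param sc `NULL` or a list: `matrix`, `metadata`, `genes` (paths),
#'   optional `cluster_col`, `clusters`, `gate_gene`, `query_genes`,
#'   `min_expr`.
#' @param seed Integer seed recorded for provenance (the analysis itself is
#'   deterministic; the seed governs any simulated inputs built upstream).
#' @return A list of class `arc_run_config`.
#' @export
run_config <- function(ephys = NULL, image = NULL, sc = NULL, seed = 1) {
  defaults <- list(
    ephys = list(bin_width_s = 10, baseline_window_s = 300,
                 drug_window_s = 300, k = 3),
    image = list(min_size_um2 = 20, median_radius = 2, dot_threshold = 0.25,
                 min_sep_px = 3, positive_min_dots = 3),
    sc = list(cluster_col = "cluster", min_expr = 0)
  )
  fill <- function(user, def) {
    if (is.null(user)) return(NULL)
    utils::modifyList(def, user)
  }
  structure(
    list(ephys = fill(ephys, defaults$ephys),
         image = fill(image, defaults$image),
         sc = fill(sc, defaults$sc),
         seed = as.integer(seed)),
    class = "arc_run_config"
  )
}

#' @rdname run_config
#' @param path YAML config path.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort(paste0("config file not found: ", path))
  y <- yaml::read_yaml(path)
  run_config(ephys = y$ephys, image = y$image, sc = y$sc,
             seed = y$seed %||% 1)
}

#' Run the full analysis pipeline from a configuration
#'
#' Executes the configured stages (electrophysiology classification, image
#' quantification, single-cell subset counting), writes all documented
#' output tables into `out_dir`, and records provenance (package version,
#' effective config, input checksums). Outputs are deterministic for fixed
#' inputs and config; any stage error aborts with the stage name attached.
#'
#' Files written (per configured stage): `calls.csv`,
#' `population_summary.csv` / `.json`, `heatmap_delta.csv`,
#' `heatmap_z.csv`; `cells.csv`, `coexpression.csv` / `.json`,
#' `roi_masks.tif`; `subset_report.json` / `subset_report.csv`;
#' always `config.yaml` and `provenance.yaml`.
#'
#' @param config An `arc_run_config` (or path to a YAML config).
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a named list of the in-memory results per stage.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "arc_run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  results <- list()
  inputs <- character(0)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("stage '", name, "' failed: ", conditionMessage(e)))
    })
  }
  need <- function(path, what) {
    if (is.null(path)) abort(paste0("config entry missing: ", what))
    if (!file.exists(path)) {
      abort(paste0(what, " file not found: ", path))
    }
    inputs[[length(inputs) + 1]] <<- path
    path
  }

  if (!is.null(config$ephys)) {
    results$ephys <- stage("ephys", {
      e <- config$ephys
      io <- read_spike_table(need(e$spikes, "ephys spikes"),
                             need(e$protocol, "ephys protocol"),
                             if (!is.null(e$vm)) need(e$vm, "ephys vm"))
      calls <- classify_responses(io$spikes, io$protocol, vm = io$vm,
                                  bin_width_s = e$bin_width_s,
                                  baseline_window_s = e$baseline_window_s,
                                  drug_window_s = e$drug_window_s, k = e$k)
      readr::write_csv(calls, file.path(out_dir, "calls.csv"))
      summary <- render_summary_tables(calls, out_dir)
      hm <- response_heatmap_table(io$spikes, io$protocol,
                                   bin_width_s = e$bin_width_s,
                                   baseline_window_s = e$baseline_window_s)
      mats <- heatmap_matrices(hm)
      write_matrix_csv(mats$delta, file.path(out_dir, "heatmap_delta.csv"))
      write_matrix_csv(mats$z, file.path(out_dir, "heatmap_z.csv"))
      list(calls = calls, summary = summary, heatmap = hm)
    })
  }

  if (!is.null(config$image)) {
    results$image <- stage("image", {
      im <- config$image
      img <- read_channel_image(need(im$path, "image"), im$sidecar)
      q <- quantify_image(
        img, im$seed_channel,
        channels = im$channels %||% setdiff(names(img$channels),
                                            im$seed_channel),
        min_size_um2 = im$min_size_um2, median_radius = im$median_radius,
        dot_threshold = im$dot_threshold, min_sep_px = im$min_sep_px,
        positive_min_dots = im$positive_min_dots,
        exclude_rois = if (!is.null(im$exclude)) {
          need(im$exclude, "image exclusion list")
        }
      )
      readr::write_csv(q$cells, file.path(out_dir, "cells.csv"))
      write_label_mask(q$labels, file.path(out_dir, "roi_masks.tif"))
      coex <- NULL
      if (!is.null(im$reference) && !is.null(im$queries)) {
        coex <- coexpression_table(q$cells, im$reference, im$queries)
        readr::write_csv(coex, file.path(out_dir, "coexpression.csv"))
        jsonlite::write_json(coex, file.path(out_dir, "coexpression.json"),
                             digits = NA, auto_unbox = TRUE, pretty = TRUE)
      }
      list(cells = q$cells, rois = q$rois, coexpression = coex)
    })
  }

  if (!is.null(config$sc)) {
    results$sc <- stage("sc", {
      s <- config$sc
      counts <- read_count_matrix(need(s$matrix, "sc matrix"),
                                  need(s$metadata, "sc metadata"),
                                  if (!is.null(s$genes)) {
                                    need(s$genes, "sc genes")
                                  },
                                  cluster_col = s$cluster_col)
      rep <- subset_report(counts, s$clusters, s$gate_gene, s$query_genes,
                           min_expr = s$min_expr)
      readr::write_csv(rep$per_gene, file.path(out_dir, "subset_report.csv"))
      jsonlite::write_json(
        list(clusters = rep$clusters, n_in_clusters = rep$n_in_clusters,
             n_filtered = rep$n_filtered, gate_gene = rep$gate_gene,
             per_gene = rep$per_gene),
        file.path(out_dir, "subset_report.json"),
        digits = NA, auto_unbox = TRUE, pretty = TRUE
      )
      rep
    })
  }

  yaml::write_yaml(unclass(config), file.path(out_dir, "config.yaml"))
  cfg_tmp <- file.path(out_dir, "config.yaml")
  yaml::write_yaml(
    list(package = "arcquant",
         version = as.character(packageVersion("arcquant")),
         config_md5 = unname(tools::md5sum(cfg_tmp)),
         inputs = as.list(setNames(unname(tools::md5sum(inputs)), inputs))),
    file.path(out_dir, "provenance.yaml")
  )
  invisible(results)
}

#' Publication-style per-concentration response tables
#'
#' Formats response calls as one row per (agent, concentration) with class
#' percentages to one decimal place, in the fixed column order excited /
#' not responsive / inhibited, and optionally writes CSV and JSON copies.
#' Rounding keeps each row's percentages summing to 100 +- 0.1.
#'
#' @param calls Output of [classify_responses()] (an empty table produces a
#'   header-only file with a warning).
#' @param out_dir Optional directory for `population_summary.csv` /
#'   `.json`.
#' @return The formatted summary tibble.
#' @export
render_summary_tables <- function(calls, out_dir = NULL) {
  if (!nrow(calls)) {
    warn("no response calls; writing header-only summary")
    out <- tibble(agent = character(), concentration_uM = numeric(),
                  n = integer(), pct_excited = numeric(),
                  pct_not_responsive = numeric(), pct_inhibited = numeric())
  } else {
    out <- summarize_population(calls) %>%
      dplyr::transmute(
        .data$agent, .data$concentration_uM, .data$n,
        pct_excited = round(.data$pct_excited, 1),
        pct_not_responsive = round(.data$pct_not_responsive, 1),
        pct_inhibited = round(.data$pct_inhibited, 1)
      )
  }
  if (!is.null(out_dir)) {
    readr::write_csv(out, file.path(out_dir, "population_summary.csv"))
    jsonlite::write_json(out, file.path(out_dir, "population_summary.json"),
                         digits = NA, auto_unbox = TRUE, pretty = TRUE)
  }
  out
}

# neuron x bin matrix as CSV with a neuron_id key column
write_matrix_csv <- function(m, path) {
  d <- as_tibble(m, .name_repair = "minimal")
  names(d) <- paste0("bin_", seq_len(ncol(m)))
  readr::write_csv(dplyr::bind_cols(tibble(neuron_id = rownames(m)), d),
                   path)
}
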