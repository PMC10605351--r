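#' @title Batch pipeline
#' @name pipeline
#' @description
#' [run_pipeline()] chains segmentation, background elimination,
#' per-nucleus quantification, granularity analysis and group
#' statistics over a batch of images described by one configuration.
#' The `(image_id, nucleus_label)` pair is the universal join key
#' across all output tables; every QC exclusion and every parameter
#' value used is recorded in the run log. The analysis itself is
#' deterministic; the config seed only feeds simulation.
NULL

default_config <- function() {
  list(
    pixel_edge_nm = 25.88,
    bit_depth = 12L,
    segmentation = list(min_area_um2 = 20, connectivity = 8,
                        min_mean_intensity = 0),
    granularity = list(n_bins = 256, max_passes = 1000,
                       min_mode_frac = 0.001, max_valley_ratio = 0.5,
                       median_window = 3,
                       connectivity = 8, min_size_px = 5),
    seed = 1L
  )
}

#' Read and validate a pipeline run configuration
#'
#' The YAML config holds the image manifest (`images`: list of
#' `path` / `group` / optional `id` entries), the `channel_map`
#' (role -> TIFF page), the calibration (`pixel_edge_nm`, `bit_depth`),
#' optional `segmentation` and `granularity` parameter blocks,
#' `out_dir` and `seed`. Missing parameters take the package defaults.
#'
#' @param path Path to a YAML file, or an already-parsed list.
#' @return A validated `RunConfig` list.
#' @export
read_run_config <- function(path) {
  cfg <- if (is.character(path)) yaml::read_yaml(path) else path
  base <- default_config()
  for (blk in c("segmentation", "granularity")) {
    cfg[[blk]] <- utils::modifyList(base[[blk]], cfg[[blk]] %||% list())
  }
  for (key in c("pixel_edge_nm", "bit_depth", "seed")) {
    cfg[[key]] <- cfg[[key]] %||% base[[key]]
  }
  if (is.null(cfg$images) || !length(cfg$images)) {
    stop("config must list at least one image", call. = FALSE)
  }
  if (is.null(cfg$channel_map)) {
    stop("config must provide a channel_map (role -> page)", call. = FALSE)
  }
  for (img in cfg$images) {
    if (is.null(img$path) || is.null(img$group)) {
      stop("every image entry needs `path` and `group`", call. = FALSE)
    }
    if (!file.exists(img$path)) {
      stop("image file not found: ", img$path, call. = FALSE)
    }
  }
  structure(cfg, class = "RunConfig")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full analysis pipeline over a batch of images
#'
#' For each manifest image: read, segment nuclei, eliminate
#' extranuclear background, quantify per-nucleus amounts, and analyse
#' granularity for every label channel present. Per-nucleus metrics
#' are then pooled by group and compared pairwise (nucleus area with
#' the two-sample t-test, all other metrics with Kruskal-Wallis), and
#' per-group boxplot summaries are emitted. A failing image is
#' reported and skipped; the remaining images are still processed.
#'
#' @param config A `RunConfig` (or path / list accepted by
#'   [read_run_config()]).
#' @param out_dir Output directory; overrides `config$out_dir`.
#' @return Invisibly, a list with all result tables (`nuclei`,
#'   `metrics`, `granules`, `granularity`, `thresholds`,
#'   `comparisons`, `boxplots`), the written file `paths`, the run
#'   `log` and `failures` (data frame of failed images, empty on full
#'   success).
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (!inherits(config, "RunConfig")) config <- read_run_config(config)
  out_dir <- out_dir %||% config$out_dir
  if (is.null(out_dir)) stop("no output directory given", call. = FALSE)

  log <- c(paste0("chromagrain run ", format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
           paste0("pixel_edge_nm=", config$pixel_edge_nm,
                  " bit_depth=", config$bit_depth,
                  " seed=", config$seed),
           paste0("segmentation: ",
                  paste(names(config$segmentation), config$segmentation,
                        sep = "=", collapse = " ")),
           paste0("granularity: ",
                  paste(names(config$granularity), config$granularity,
                        sep = "=", collapse = " ")))
  seg <- config$segmentation
  grn <- config$granularity
  nuclei <- list(); metrics <- list(); granules <- list()
  summaries <- list(); thresholds <- list(); failures <- list()

  for (img_cfg in config$images) {
    id <- img_cfg$id %||% basename(img_cfg$path)
    res <- tryCatch({
      image <- read_multichannel_image(
        img_cfg$path, channel_map = unlist(config$channel_map),
        pixel_edge_nm = config$pixel_edge_nm,
        bit_depth = config$bit_depth, source_id = id)
      masks <- segment_nuclei(image$channels$dna,
                              min_area_um2 = seg$min_area_um2,
                              pixel_edge_nm = config$pixel_edge_nm,
                              bit_depth = config$bit_depth,
                              connectivity = seg$connectivity)
      label_roles <- setdiff(names(image$channels), "dna")
      image <- mask_background(image, masks)
      if (seg$min_mean_intensity > 0) {
        for (role in label_roles) {
          masks <- flag_weak_signal(image$channels[[role]], masks,
                                    seg$min_mean_intensity)
        }
      }
      for (i in seq_len(nrow(masks$nuclei))) {
        if (!masks$nuclei$qc_pass[i]) {
          log <- c(log, paste0("QC exclude image=", id, " nucleus=",
                                masks$nuclei$label[i], " reason=",
                                masks$nuclei$qc_reason[i]))
        }
      }
      met <- quantify_nuclei(image, masks, channels = label_roles)
      g_all <- list(); s_all <- list(); t_all <- list()
      for (role in label_roles) {
        ga <- analyze_granularity(
          image, masks, role, n_bins = grn$n_bins,
          max_passes = grn$max_passes, min_mode_frac = grn$min_mode_frac,
          max_valley_ratio = grn$max_valley_ratio,
          median_window = grn$median_window,
          connectivity = grn$connectivity, min_size_px = grn$min_size_px)
        nb <- ga$thresholds$nucleus_label[!ga$thresholds$bimodal]
        for (lab in nb) {
          log <- c(log, paste0("QC exclude image=", id, " nucleus=", lab,
                                " channel=", role,
                                " reason=NO_GRANULATION"))
        }
        g_all[[role]] <- ga$granules
        s_all[[role]] <- ga$summary
        t_all[[role]] <- ga$thresholds
      }
      list(id = id, group = img_cfg$group, masks = masks, metrics = met,
           granules = do.call(rbind, g_all),
           summary = do.call(rbind, s_all),
           thresholds = do.call(rbind, t_all))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      log <- c(log, paste0("FAILED image=", id, ": ", conditionMessage(res)))
      failures[[length(failures) + 1]] <-
        data.frame(image_id = id, error = conditionMessage(res))
      next
    }
    tag <- function(df) {
      if (is.null(df) || !nrow(df)) return(df)
      cbind(data.frame(image_id = res$id, group = res$group), df)
    }
    nuc_rec <- res$masks$nuclei
    names(nuc_rec)[names(nuc_rec) == "label"] <- "nucleus_label"
    nuclei[[id]] <- tag(nuc_rec)
    metrics[[id]] <- tag(res$metrics)
    granules[[id]] <- tag(res$granules)
    summaries[[id]] <- tag(res$summary)
    thresholds[[id]] <- tag(res$thresholds)
    log <- c(log, paste0("done image=", id, " nuclei=",
                         nrow(res$masks$nuclei), " pass=",
                         sum(res$masks$nuclei$qc_pass)))
  }

  bind <- function(lst) if (length(lst)) do.call(rbind, c(lst, list(make.row.names = FALSE))) else NULL
  tables <- list(nuclei = bind(nuclei), metrics = bind(metrics),
                 granules = bind(granules), granularity = bind(summaries),
                 thresholds = bind(thresholds))

  # ---- group statistics -------------------------------------------
  comparisons <- list(); boxplots <- list()
  met <- tables$metrics
  if (!is.null(met) && length(unique(met$group)) >= 2) {
    add <- function(df, col, kind) {
      comparisons[[length(comparisons) + 1]] <<-
        compare_all_pairs(df, col, "group", metric_kind = kind)
      boxplots[[length(boxplots) + 1]] <<- boxplot_table(df, col, "group")
    }
    add(met, "area_um2", "nucleus_size")
    for (col in grep("^amount_(?!um2)", names(met), value = TRUE, perl = TRUE)) {
      add(met, col, "other")
    }
    gsum <- tables$granularity
    if (!is.null(gsum) && nrow(gsum)) {
      for (role in unique(gsum$channel)) {
        sub <- gsum[gsum$channel == role, ]
        for (col in c("n_granules", "mean_area_px",
                      "pixelwise_mean_intensity")) {
          sub2 <- sub
          nm <- paste0(col, "_", role)
          sub2[[nm]] <- sub2[[col]]
          add(sub2, nm, "other")
        }
      }
    }
  }
  tables$comparisons <- if (length(comparisons)) {
    do.call(rbind, c(comparisons, list(make.row.names = FALSE)))
  } else NULL
  tables$boxplots <- if (length(boxplots)) {
    do.call(rbind, c(boxplots, list(make.row.names = FALSE)))
  } else NULL

  tables <- Filter(Negate(is.null), tables)
  paths <- write_tables(tables, out_dir)
  log_path <- file.path(out_dir, "run_log.txt")
  writeLines(log, log_path)
  fail_df <- if (length(failures)) do.call(rbind, failures) else
    data.frame(image_id = character(0), error = character(0))
  invisible(list(tables = tables, paths = c(paths, log = log_path),
                 log = log, failures = fail_df))
}
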