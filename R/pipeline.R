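#' Pipeline run configuration
#'
#' Bundles the stage toggles, phantom defaults, network configuration and
#' statistics options of one reproducible run. A single global seed fans out
#' to per-stage seeds through a counter-based scheme, so stages can be rerun
#' independently yet reproducibly.
#'
#' @param outdir Output directory (one subdirectory per stage).
#' @param seed Global seed.
#' @param n_per_group Integer length-3: phantoms per group
#'   (control/non-ACLD/ACLD) for the imaging arm.
#' @param n_train Cases used for network training (taken from the start of
#'   the phantom list); the rest are segmented by the trained model.
#' @param cohort_sizes Integer length-3 for the tabular cohort.
#' @param stages Character subset of
#'   `c("simulate", "train", "segment", "metrics", "stats")`.
#' @param unet A [unet_config()].
#' @param phantom Named list of [phantom_spec()] overrides (geometry, noise).
#' @param use_gt_organs Keep ground-truth organ masks when quantifying
#'   predictions, so vessel metrics isolate vessel-segmentation error.
#' @return A `run_config`.
#' @export
run_config <- function(outdir = tempfile("hepavol_run_"), seed = 1L,
                       n_per_group = c(2L, 2L, 2L), n_train = 4L,
                       cohort_sizes = c(35L, 44L, 118L),
                       stages = c("simulate", "train", "segment", "metrics",
                                  "stats"),
                       unet = unet_config(patch_size = c(32L, 24L, 16L),
                                          stride = c(16L, 12L, 8L),
                                          base_channels = 8L, epochs = 40L),
                       phantom = list(grid_shape = c(32L, 24L, 16L),
                                      spacing_mm = c(5, 5, 6),
                                      liver_axes_mm = c(58, 42, 34),
                                      noise_sigma = 0),
                       use_gt_organs = TRUE) {
  structure(list(outdir = outdir, seed = as.integer(seed),
                 n_per_group = as.integer(n_per_group),
                 n_train = as.integer(n_train),
                 cohort_sizes = as.integer(cohort_sizes),
                 stages = stages, unet = unet, phantom = phantom,
                 use_gt_organs = use_gt_organs),
            class = "run_config")
}

stage_dir <- function(config, stage) {
  d <- file.path(config$outdir, stage)
  dir.create(d, recursive = TRUE, showWarnings = FALSE)
  d
}

manifest_path <- function(config) file.path(config$outdir, "manifest.json")

read_manifest <- function(config) {
  p <- manifest_path(config)
  if (file.exists(p)) jsonlite::read_json(p, simplifyVector = TRUE)
  else list(stages = list())
}

write_manifest <- function(config, manifest) {
  jsonlite::write_json(manifest, manifest_path(config), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, null = "null")
}

config_hash <- function(config) {
  tf <- tempfile(fileext = ".yaml")
  on.exit(unlink(tf))
  ser <- config
  ser$unet <- unclass(ser$unet)
  ser$outdir <- NULL # hash the scientific content, not the location
  yaml::write_yaml(ser, tf)
  unname(tools::md5sum(tf))
}

checksum_files <- function(paths) {
  as.list(tools::md5sum(sort(paths[file.exists(paths)])))
}

#' Run the simulate -> train -> segment -> metrics -> stats pipeline
#'
#' Executes the configured stages, writing per-stage outputs (NIfTI volumes,
#' CSV tables, JSON reports) under `config$outdir` and a manifest recording
#' the configuration hash, per-stage seeds and output checksums. Stages
#' whose outputs already exist and whose config hash matches are skipped,
#' so partial reruns resume from completed stages; a stage whose inputs are
#' missing aborts with an error naming the stage to rerun.
#'
#' @param config A [run_config()].
#' @return The manifest (invisibly), with elements per executed stage.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(config)
  manifest <- read_manifest(config)
  if (!is.null(manifest$config_hash) && !identical(manifest$config_hash, hash))
    manifest <- list(stages = list()) # config changed: start over
  manifest$config_hash <- hash
  manifest$seed <- config$seed
  manifest$versions <- list(
    hepavol = as.character(utils::packageVersion("hepavol")),
    R = paste(R.version$major, R.version$minor, sep = "."))

  done <- function(stage) {
    st <- manifest$stages[[stage]]
    !is.null(st) && isTRUE(st$complete)
  }
  record <- function(stage, outputs, extra = list()) {
    manifest$stages[[stage]] <<- c(list(complete = TRUE,
                                        seed = child_seed(config$seed, stage),
                                        checksums = checksum_files(outputs)),
                                   extra)
    write_manifest(config, manifest)
  }
  need <- function(stage, paths) {
    missing <- paths[!file.exists(paths)]
    if (length(missing))
      stop_hepavol("hepavol_missing_stage",
                   "missing artifacts %s: rerun stage '%s'",
                   paste(basename(missing), collapse = ", "), stage)
  }

  groups <- c("control", "non-ACLD", "ACLD")
  n_img <- sum(config$n_per_group)
  sim_dir <- file.path(config$outdir, "simulate")
  cohort_csv <- file.path(sim_dir, "cohort.csv")
  img_path <- function(i) file.path(sim_dir, sprintf("case%02d_image.nii.gz", i))
  lab_path <- function(i) file.path(sim_dir, sprintf("case%02d_labels.nii.gz", i))

  if ("simulate" %in% config$stages && !done("simulate")) {
    sd <- child_seed(config$seed, "simulate")
    stage_dir(config, "simulate")
    cohort <- simulate_cohort(config$cohort_sizes[1], config$cohort_sizes[2],
                              config$cohort_sizes[3], seed = sd)
    write.csv(cohort, cohort_csv, row.names = FALSE, na = "")
    img_group <- rep(groups, times = config$n_per_group)
    specs <- lapply(seq_len(n_img), function(i) {
      mg <- group_marginals()
      tg <- function(v) mg[mg$group == img_group[i] & mg$variable == v, ]
      hv <- with_seed(sd + i, {
        h <- tg("hvvr"); p <- tg("pvvr")
        ph <- lnorm_params(h$median, h$q1, h$q3)
        pp <- lnorm_params(p$median, p$q1, p$q3)
        c(rlnorm(1, ph$meanlog, ph$sdlog), rlnorm(1, pp$meanlog, pp$sdlog))
      })
      do.call(phantom_spec, c(list(target_hvvr_pct = hv[1],
                                   target_pvvr_pct = hv[2],
                                   seed = sd + 1000L + i), config$phantom))
    })
    for (i in seq_len(n_img)) {
      ph <- make_liver_phantom(specs[[i]])
      write_volume(ph$image, img_path(i))
      write_volume(ph$labels, lab_path(i))
    }
    manifest$stages$simulate <- NULL
    record("simulate",
           c(cohort_csv, vapply(seq_len(n_img), img_path, ""),
             vapply(seq_len(n_img), lab_path, "")),
           list(n_images = n_img, groups = img_group))
  }

  model_rds <- file.path(config$outdir, "train", "model.json")
  if ("train" %in% config$stages && !done("train")) {
    need("simulate", c(cohort_csv, img_path(1)))
    stage_dir(config, "train")
    train_idx <- seq_len(min(config$n_train, n_img))
    cases <- lapply(train_idx, function(i) {
      lab <- read_volume(lab_path(i), labels = TRUE)
      lab$data[lab$data > 2L] <- 0L # vessel classes only (gt organs kept aside)
      list(image = read_volume(img_path(i)), labels = lab)
    })
    cfg <- config$unet
    cfg$seed <- child_seed(config$seed, "train")
    net <- build_network(cfg)
    net <- train(net, cases)
    save_network(net, model_rds)
    record("train", model_rds, list(train_cases = train_idx,
                                    final_loss = tail(net$loss_trace, 1)))
  }

  seg_dir <- file.path(config$outdir, "segment")
  pred_path <- function(i) file.path(seg_dir, sprintf("case%02d_pred.nii.gz", i))
  if ("segment" %in% config$stages && !done("segment")) {
    need("train", model_rds)
    stage_dir(config, "segment")
    net <- load_network(model_rds)
    for (i in seq_len(n_img)) {
      vol <- read_volume(img_path(i))
      pred <- predict_volume(net, vol)
      write_volume(pred, pred_path(i))
    }
    record("segment", vapply(seq_len(n_img), pred_path, ""))
  }

  met_dir <- file.path(config$outdir, "metrics")
  vvr_csv <- file.path(met_dir, "vvr.csv")
  dice_csv <- file.path(met_dir, "dice.csv")
  if ("metrics" %in% config$stages && !done("metrics")) {
    need("segment", pred_path(1))
    stage_dir(config, "metrics")
    img_group <- rep(groups, times = config$n_per_group)
    rows <- lapply(seq_len(n_img), function(i) {
      gt <- read_volume(lab_path(i), labels = TRUE)
      pr <- read_volume(pred_path(i), labels = TRUE)
      lab <- pr$data
      if (config$use_gt_organs) { # organs from ground truth, vessels predicted
        liv <- liver_mask(gt)
        lab[(lab == 1L | lab == 2L) & !liv] <- 0L # vessels confined to liver
        lab[lab == 0L & (gt$data == 3L | gt$data == 4L)] <-
          gt$data[lab == 0L & (gt$data == 3L | gt$data == 4L)]
      }
      vv <- vessel_to_volume_ratios(label_volume(lab, gt$spacing),
                                    liver = liver_mask(gt))
      db <- dice_by_bin(pr$data == 1L | pr$data == 2L,
                        gt$data == 1L | gt$data == 2L, gt$spacing)
      list(vvr = data.frame(case = i, group = img_group[i],
                            tvvr_pct = vv$tvvr_pct, hvvr_pct = vv$hvvr_pct,
                            pvvr_pct = vv$pvvr_pct,
                            liver_volume_cc = vv$liver_volume_cc),
           dice = data.frame(case = i, group = img_group[i],
                             dice_vessel = db$overall,
                             dice_0_5 = db$by_bin[1], dice_5_10 = db$by_bin[2],
                             dice_gt10 = db$by_bin[3]))
    })
    write.csv(do.call(rbind, lapply(rows, `[[`, "vvr")), vvr_csv,
              row.names = FALSE)
    write.csv(do.call(rbind, lapply(rows, `[[`, "dice")), dice_csv,
              row.names = FALSE)
    record("metrics", c(vvr_csv, dice_csv))
  }

  stats_json <- file.path(config$outdir, "stats", "report.json")
  if ("stats" %in% config$stages && !done("stats")) {
    need("simulate", cohort_csv)
    stage_dir(config, "stats")
    cohort <- read.csv(cohort_csv, stringsAsFactors = FALSE)
    # tabular arm: measured VVRs stand in by the latent per-subject targets
    vvr <- data.frame(hvvr_pct = cohort$target_hvvr_pct,
                      pvvr_pct = cohort$target_pvvr_pct)
    vvr$tvvr_pct <- vvr$hvvr_pct + vvr$pvvr_pct
    rep <- cohort_stats(cohort, vvr)
    sub <- subgroup_analyses(cohort, vvr)
    jsonlite::write_json(stats_report_json(rep, sub), stats_json,
                         auto_unbox = TRUE, pretty = TRUE, digits = NA,
                         na = "null")
    tab2 <- table2_style(rep)
    write.csv(tab2$a, file.path(config$outdir, "stats", "vvr_by_group.csv"),
              row.names = FALSE)
    write.csv(tab2$b, file.path(config$outdir, "stats",
                                "pairwise_decreases.csv"), row.names = FALSE)
    write.csv(rep$spearman$cld, file.path(config$outdir, "stats",
                                          "correlation_map.csv"),
              row.names = FALSE)
    record("stats", stats_json)
  }
  invisible(manifest)
}

# Serializable view of a stats report (plain lists for JSON).
stats_report_json <- function(rep, sub = NULL) {
  cm <- lapply(rep$comparisons, function(cmp) {
    list(median_iqr = lapply(cmp$median_iqr, as.list),
         kruskal_wallis = cmp$kruskal_wallis,
         pairwise = cmp$pairwise,
         percent_decreases = cmp$percent_decreases)
  })
  out <- list(n = as.list(setNames(as.integer(rep$n), names(rep$n))),
              comparisons = cm, spearman = rep$spearman)
  if (!is.null(sub)) out$subgroups <- sub
  out
}

# Flatten a report into Table-2-style data.frames (a: medians, b: decreases).
table2_style <- function(rep) {
  a <- do.call(rbind, lapply(names(rep$comparisons), function(nm) {
    cmp <- rep$comparisons[[nm]]
    row <- data.frame(parameter = toupper(nm), stringsAsFactors = FALSE)
    for (g in names(cmp$median_iqr)) {
      m <- cmp$median_iqr[[g]]
      row[[g]] <- sprintf("%.1f (%.1f-%.1f)", m["median"], m["q1"], m["q3"])
    }
    row$kw_p <- cmp$kruskal_wallis$p
    row
  }))
  b <- do.call(rbind, lapply(names(rep$comparisons), function(nm) {
    cmp <- rep$comparisons[[nm]]
    data.frame(parameter = toupper(nm),
               comparison = paste(cmp$percent_decreases$from, "->",
                                  cmp$percent_decreases$to),
               percent_decrease = cmp$percent_decreases$percent_decrease,
               p_bonferroni = cmp$pairwise$p_bonferroni,
               stringsAsFactors = FALSE)
  }))
  list(a = a, b = b)
}

#' Summarise a completed run
#'
#' Collects the per-group VVR summaries, percent-decrease table, correlation
#' map and per-bin Dice table of a run directory into one plain-text report.
#' Incomplete runs yield a partial report with explicit gaps.
#'
#' @param run_dir A `run_config` outdir.
#' @return Character vector of report lines (also written to `report.txt`).
#' @export
make_report <- function(run_dir) {
  lines <- c("hepavol run report", strrep("=", 18))
  man_p <- file.path(run_dir, "manifest.json")
  if (file.exists(man_p)) {
    man <- jsonlite::read_json(man_p)
    lines <- c(lines, sprintf("config hash: %s  seed: %s",
                              man$config_hash, man$seed))
  }
  vvr_p <- file.path(run_dir, "metrics", "vvr.csv")
  if (file.exists(vvr_p)) {
    vvr <- read.csv(vvr_p)
    lines <- c(lines, "", "Vessel-to-volume ratios (measured, % of liver):")
    for (g in unique(vvr$group))
      lines <- c(lines, sprintf("  %-9s TVVR %s HVVR %s PVVR %s", g,
        paste(sprintf("%.2f", vvr$tvvr_pct[vvr$group == g]), collapse = "/"),
        paste(sprintf("%.2f", vvr$hvvr_pct[vvr$group == g]), collapse = "/"),
        paste(sprintf("%.2f", vvr$pvvr_pct[vvr$group == g]), collapse = "/")))
  } else lines <- c(lines, "", "[metrics stage absent]")
  dice_p <- file.path(run_dir, "metrics", "dice.csv")
  if (file.exists(dice_p)) {
    dc <- read.csv(dice_p)
    lines <- c(lines, "", "Vessel Dice (overall | 0-5 / 5-10 / >10 mm bins):",
               sprintf("  case %02d: %.3f | %s / %s / %s", dc$case,
                       dc$dice_vessel, sprintf("%.3f", dc$dice_0_5),
                       sprintf("%.3f", dc$dice_5_10),
                       sprintf("%.3f", dc$dice_gt10)))
  } else lines <- c(lines, "[segmentation Dice absent]")
  stats_p <- file.path(run_dir, "stats", "pairwise_decreases.csv")
  if (file.exists(stats_p)) {
    pd <- read.csv(stats_p)
    lines <- c(lines, "", "Percent decreases between group medians:",
               sprintf("  %s %-22s %6.1f%%  (corrected p = %.3g)",
                       pd$parameter, pd$comparison, pd$percent_decrease,
                       pd$p_bonferroni))
  } else lines <- c(lines, "[statistics stage absent]")
  cor_p <- file.path(run_dir, "stats", "correlation_map.csv")
  if (file.exists(cor_p)) {
    cm <- read.csv(cor_p)
    cm <- cm[is.finite(cm$rho), ]
    lines <- c(lines, "", "Spearman correlations (CLD cohort):",
               sprintf("  %-9s x %-18s rho = %+.2f (p = %.3g, n = %d)",
                       cm$vvr, cm$biomarker, cm$rho, cm$p, cm$n))
  }
  writeLines(lines, file.path(run_dir, "report.txt"))
  invisible(lines)
}

#' Save / load a network as JSON
#'
#' Weights as a flat numeric vector plus the configuration sidecar, one
#' self-contained text file.
#'
#' @param network A `unet_network`.
#' @param path Output path (`.json`).
#' @return `save_network` the path; `load_network` the network.
#' @export
save_network <- function(network, path) {
  obj <- list(config = unclass(network$config),
              params = network$params,
              loss_trace = network$loss_trace)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_network
#' @export
load_network <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- do.call(unet_config, obj$config[setdiff(names(obj$config),
                                                 "in_channels")])
  net <- build_network(cfg)
  net$params <- as.numeric(obj$params)
  net$loss_trace <- obj$loss_trace
  net
}
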