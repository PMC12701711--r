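#' Stack-height / stack-count combination table
#'
#' The default entries allow up to 4 phase-binning stacks and 8 interpolated
#' intervals at height 4, up to 2 and 4 at height 8, and 1 and 2 at height
#' 16 - seven (h, NPB) combinations in total.
#'
#' @param entries data.frame with columns `h`, `npb_max`, `nint_max`.
#' @return the validated data.frame (class `combination_spec`).
#' @export
combination_spec <- function(entries = data.frame(h = c(4, 8, 16),
                                                  npb_max = c(4, 2, 1),
                                                  nint_max = c(8, 4, 2))) {
  if (anyDuplicated(entries$h)) stop("stack heights must be distinct")
  if (any(entries$npb_max < 1) || any(entries$nint_max < 1))
    stop("combination maxima must be >= 1")
  structure(entries, class = c("combination_spec", "data.frame"))
}

#' Enumerate all (h, NPB) combinations
#'
#' @param spec a [combination_spec()].
#' @return data.frame with columns `h` and `npb`, ascending in `h` then
#'   `npb` (7 rows for the default spec).
#' @export
enumerate_combinations <- function(spec = combination_spec()) {
  rows <- lapply(seq_len(nrow(spec)), function(i)
    data.frame(h = spec$h[i], npb = seq_len(spec$npb_max[i])))
  out <- do.call(rbind, rows)
  out[order(out$h, out$npb), , drop = FALSE]
}

#' Choose a secondary phase for artifact infusion
#'
#' Implements the three pairing criteria on a 10-phase cycle: `opposite`
#' (half a cycle away, e.g. T80 for T30), `opposite_nbhd` (uniform over the
#' opposite phase and its +-2 neighbours, e.g. \{T60, T70, T80, T90, T00\}
#' for T30), and `random` (uniform over the 9 other phases).
#'
#' @param phase phase label (`"T00"`..`"T90"`).
#' @param pairing `"opposite"`, `"opposite_nbhd"` or `"random"`.
#' @param seed RNG seed (used by the stochastic criteria).
#' @return a phase label.
#' @export
choose_secondary_phase <- function(phase,
                                   pairing = c("opposite", "opposite_nbhd",
                                               "random"),
                                   seed = NULL) {
  pairing <- match.arg(pairing)
  labels <- phase_labels(10)
  i <- match(phase, labels)
  if (is.na(i)) stop(sprintf("unknown phase label '%s'", phase))
  opp <- ((i - 1 + 5) %% 10) + 1
  with_seed(seed, switch(pairing,
    opposite = labels[opp],
    opposite_nbhd = labels[((opp - 1 + sample(-2:2, 1)) %% 10) + 1],
    random = sample(labels[-i], 1)))
}

#' Split clean cases into template / untouched and train / test
#'
#' First partitions the clean cases 0.85/0.15 into templates (to be infused
#' with artifacts) and untouched test-only negatives, then partitions the
#' templates 0.85/0.15 into train and test templates. Sizes use
#' round-half-up at each partition.
#'
#' @param n_clean number of clean cases (>= 3).
#' @param template_split,train_split fractions in (0, 1) (defaults 0.85).
#' @param seed RNG seed for the random assignment.
#' @return list with integer index vectors `train_templates`,
#'   `test_templates`, `untouched`.
#' @export
split_templates <- function(n_clean, template_split = 0.85,
                            train_split = 0.85, seed = 1L) {
  if (n_clean < 3) stop("need at least 3 clean cases")
  rhu <- function(x) floor(x + 0.5)
  n_templates <- rhu(template_split * n_clean)
  n_train <- rhu(train_split * n_templates)
  with_seed(seed, {
    perm <- sample(n_clean)
    templates <- perm[seq_len(n_templates)]
    list(train_templates = sort(templates[seq_len(n_train)]),
         test_templates = sort(templates[-seq_len(n_train)]),
         untouched = sort(perm[-seq_len(n_templates)]))
  })
}

#' Foreground oversampling rate schedule
#'
#' Exponential decay of the foreground oversampling rate used when training
#' on class-imbalanced artifact data:
#' `R(e) = r_target + (r_initial - r_target) * exp(-k (e - e_start))` for
#' `e >= e_start`, and `r_initial` before `e_start`.
#'
#' @param e epoch (vectorized, >= 0).
#' @param r_initial initial rate (default 0.8).
#' @param r_target asymptotic target rate (default 0.4).
#' @param e_start epoch at which decay begins (default 5).
#' @param decay_k decay rate constant (> 0).
#' @return rate(s) in \[r_target, r_initial\].
#' @export
oversampling_rate <- function(e, r_initial = 0.8, r_target = 0.4,
                              e_start = 5, decay_k = 0.1) {
  if (decay_k <= 0) stop("decay_k must be > 0")
  if (r_initial < r_target) stop("r_initial must be >= r_target")
  if (any(e < 0)) stop("epoch must be >= 0")
  ifelse(e < e_start, r_initial,
         r_target + (r_initial - r_target) * exp(-decay_k * (e - e_start)))
}

#' Build configuration for synthetic datasets
#'
#' @param pairing secondary-phase criterion (see [choose_secondary_phase()]).
#' @param nc_train,nc_test cycles through the combination table per train /
#'   test template (defaults 4 and 1).
#' @param template_split,train_split partition fractions (defaults 0.85).
#' @param p_zero_interp probability that a case receives no interpolation
#'   artifacts (default 0.3).
#' @param sigma_g_range log-uniform sampling range of the artifact
#'   visibility (default \[0.5, 3\]).
#' @param lr_split also emit left/right-cropped duplicates.
#' @param seed RNG seed.
#' @return list of class `build_config`.
#' @export
build_config <- function(pairing = "opposite_nbhd", nc_train = 4, nc_test = 1,
                         template_split = 0.85, train_split = 0.85,
                         p_zero_interp = 0.3, sigma_g_range = c(0.5, 3),
                         lr_split = FALSE, seed = 1L) {
  if (nc_train < nc_test || nc_test < 1) stop("need nc_train >= nc_test >= 1")
  if (template_split <= 0 || template_split >= 1 ||
      train_split <= 0 || train_split >= 1)
    stop("split fractions must lie in (0, 1)")
  structure(list(pairing = pairing, nc_train = nc_train, nc_test = nc_test,
                 template_split = template_split, train_split = train_split,
                 p_zero_interp = p_zero_interp, sigma_g_range = sigma_g_range,
                 lr_split = lr_split, seed = as.integer(seed)),
            class = "build_config")
}

#' Assemble a synthetic artifact dataset from clean phantom series
#'
#' For every train/test template and every (h, NPB) combination, cycles
#' `nc_train` (or `nc_test`) times: draws an artifact visibility sigma_g
#' (log-uniform), picks a primary phase at random and a secondary phase by
#' the pairing criterion, infuses phase-binning artifacts (re-drawing the
#' secondary phase when the admissibility condition rejects the pairing),
#' optionally infuses interpolation artifacts (`NINT` uniform in
#' `1..nint_max(h)` with probability `1 - p_zero_interp`, else 0), and
#' combines the masks (phase-binning label wins on overlap). Untouched
#' cases are emitted as artifact-free test negatives. Volumes are written as
#' NIfTI with a JSON-lines manifest when `out_dir` is given; the returned
#' manifest always carries the case records and, when `keep_volumes`, the
#' in-memory cases themselves.
#'
#' @param series_list list of [generate_phase_series()] results
#'   (pre-processing to the normalized domain happens internally).
#' @param cfg a [build_config()].
#' @param comb a [combination_spec()].
#' @param out_dir optional output directory for NIfTI + manifest files.
#' @param keep_volumes keep generated volumes/masks in the result (default
#'   TRUE when `out_dir` is NULL).
#' @return list of class `dataset_manifest`: `cases` (data.frame), `summary`
#'   (per-split artifact volume %% and slice statistics with 95%% CI), and
#'   optionally `volumes` (list of cases with `volume`, `mask`, `lung`,
#'   `region`).
#' @export
build_dataset <- function(series_list, cfg = build_config(),
                          comb = combination_spec(), out_dir = NULL,
                          keep_volumes = is.null(out_dir)) {
  splits <- split_templates(length(series_list), cfg$template_split,
                            cfg$train_split, seed = cfg$seed)
  combos <- enumerate_combinations(comb)
  records <- list(); volumes <- list()
  case_id <- 0L
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  emit <- function(rec, case) {
    case_id <<- case_id + 1L
    rec$case_id <- case_id
    if (!is.null(out_dir)) {
      base <- file.path(out_dir, sprintf("case%04d", case_id))
      write_volume(case$volume, paste0(base, "_img.nii.gz"))
      write_mask(case$mask$data, case$volume$spacing, paste0(base, "_artifact.nii.gz"))
      write_mask(case$lung$data, case$volume$spacing, paste0(base, "_lung.nii.gz"))
      rec$path <- base
    }
    records[[case_id]] <<- as.data.frame(rec)
    if (keep_volumes) volumes[[case_id]] <<- case
  }

  make_cases <- function(template_ids, nc, split_tag, offset) {
    for (ti in seq_along(template_ids)) {
      series <- series_list[[template_ids[ti]]]
      norm <- lapply(series$phases, function(p)
        list(volume = truncate_and_normalize(p$volume), mask = p$mask))
      labels <- names(series$phases)
      for (ci in seq_len(nrow(combos))) {
        for (cyc in seq_len(nc)) {
          sd0 <- derive_seed(cfg$seed, paste(split_tag, "case"),
                             offset + ((ti - 1) * nrow(combos) + ci - 1) * nc + cyc)
          pars <- with_seed(sd0, list(
            sigma_g = exp(stats::runif(1, log(cfg$sigma_g_range[1]),
                                       log(cfg$sigma_g_range[2]))),
            primary = sample(labels, 1),
            u_interp = stats::runif(1),
            nint_draw = stats::runif(1)))
          primary <- norm[[pars$primary]]
          pb_result <- NULL; secondary_label <- NA
          for (attempt in 1:5) {
            sec_lab <- choose_secondary_phase(pars$primary, cfg$pairing,
                                              seed = derive_seed(sd0, "phase", attempt))
            if (!sec_lab %in% labels || sec_lab == pars$primary) next
            pp <- pb_params(h = combos$h[ci], n_stacks = combos$npb[ci],
                            sigma_g = pars$sigma_g,
                            seed = derive_seed(sd0, "pb", attempt))
            # stacks may not fit a small lung at this phase/height: skip draw
            res <- tryCatch(
              infuse_phase_binning(primary$volume, norm[[sec_lab]]$volume,
                                   primary$mask, pp),
              error = function(e) list(accepted = FALSE))
            if (res$accepted) { pb_result <- res; secondary_label <- sec_lab; break }
          }
          if (is.null(pb_result)) next  # no admissible pairing; skip (logged in manifest summary)
          vol <- pb_result$volume
          mask <- pb_result$mask$data
          nint_max <- comb$nint_max[match(combos$h[ci], comb$h)]
          nint <- 0L
          if (pars$u_interp > cfg$p_zero_interp)
            nint <- 1L + floor(pars$nint_draw * nint_max)
          if (nint > 0) {
            ip <- interp_params(h = combos$h[ci] + 2L, n_intervals = nint,
                                sigma_g = pars$sigma_g,
                                seed = derive_seed(sd0, "interp"))
            ivs <- perturb_intervals(ip, dim(vol$data)[3])
            ir <- infuse_interpolation(vol, ivs)
            vol <- ir$volume
            mask[mask == 0L & ir$mask$data == 2L] <- 2L  # PB label wins on overlap
          }
          region <- make_region_mask(primary$mask, 3)
          lung_vox <- sum(primary$mask$data > 0)
          case <- list(volume = vol,
                       mask = artifact_mask(array(mask, dim(mask))),
                       lung = primary$mask, region = region)
          emit(list(split = split_tag, template = template_ids[ti],
                    primary = pars$primary, secondary = secondary_label,
                    h = combos$h[ci], npb = combos$npb[ci], nint = nint,
                    sigma_g = pars$sigma_g,
                    pb_voxels = sum(mask == 1L), int_voxels = sum(mask == 2L),
                    pb_volume_pct = 100 * sum(mask == 1L) / lung_vox,
                    int_volume_pct = 100 * sum(mask == 2L) / lung_vox,
                    pb_slices = sum(apply(mask == 1L, 3, any)),
                    int_slices = sum(apply(mask == 2L, 3, any))),
               case)
        }
      }
    }
  }

  make_cases(splits$train_templates, cfg$nc_train, "train", 0L)
  make_cases(splits$test_templates, cfg$nc_test, "test", 1000000L)
  # untouched negatives
  for (ui in splits$untouched) {
    series <- series_list[[ui]]
    p <- series$phases[[1]]
    voln <- truncate_and_normalize(p$volume)
    case <- list(volume = voln,
                 mask = artifact_mask(array(0L, dim(voln$data))),
                 lung = p$mask, region = make_region_mask(p$mask, 3))
    emit(list(split = "untouched", template = ui, primary = p$label,
              secondary = NA, h = NA, npb = 0L, nint = 0L, sigma_g = NA,
              pb_voxels = 0L, int_voxels = 0L, pb_volume_pct = 0,
              int_volume_pct = 0, pb_slices = 0L, int_slices = 0L),
         case)
  }

  cases <- do.call(rbind, records)
  rownames(cases) <- NULL
  if (!is.null(out_dir))
    writeLines(vapply(seq_len(nrow(cases)), function(i)
      jsonlite::toJSON(as.list(cases[i, ]), auto_unbox = TRUE, na = "null"),
      character(1)), file.path(out_dir, "manifest.jsonl"))
  structure(list(cases = cases, summary = dataset_summary(cases),
                 volumes = if (keep_volumes) volumes else NULL,
                 splits = splits),
            class = "dataset_manifest")
}

# Table-2-style per-split summary: mean artifact volume % and slices, 95% CI.
dataset_summary <- function(cases) {
  infused <- cases[cases$split != "untouched", , drop = FALSE]
  ci95 <- function(x) if (length(x) > 1) 1.96 * stats::sd(x) / sqrt(length(x)) else NA_real_
  do.call(rbind, lapply(split(infused, infused$split), function(d) {
    data.frame(split = d$split[1], n_cases = nrow(d),
               pb_volume_pct = mean(d$pb_volume_pct),
               pb_volume_pct_ci = ci95(d$pb_volume_pct),
               int_volume_pct = mean(d$int_volume_pct),
               int_volume_pct_ci = ci95(d$int_volume_pct),
               pb_slices = mean(d$pb_slices), int_slices = mean(d$int_slices))
  }))
}

#' @export
print.dataset_manifest <- function(x, ...) {
  cat(sprintf("<dataset_manifest> %d cases (%s)\n", nrow(x$cases),
              paste(sprintf("%s: %d", names(table(x$cases$split)),
                            table(x$cases$split)), collapse = ", ")))
  invisible(x)
}
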