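# Frame files are JSON-lines: one object per conformation with frame
# metadata, the site table and the coupling matrix as sparse 0-based
# upper-triangle triplets. TSV outputs use '.' decimals and 6-decimal
# floats so runs diff cleanly.

#' Write per-frame titration models as JSON-lines
#'
#' @param frames list of frame records: `list(frame_id, replicate,
#'   time_ps, ensemble, model)` with `model` a [titration_model()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_frames <- function(frames, path) {
  lines <- vapply(frames, function(fr) {
    w <- fr$model$w
    trip <- which(upper.tri(w) & w != 0, arr.ind = TRUE)
    wlist <- lapply(seq_len(nrow(trip)), function(k)
      list(trip[k, 1] - 1L, trip[k, 2] - 1L, w[trip[k, 1], trip[k, 2]]))
    jsonlite::toJSON(list(
      frame_id = fr$frame_id, replicate = fr$replicate,
      time_ps = fr$time_ps, ensemble = fr$ensemble,
      sites = lapply(seq_len(nrow(fr$model$sites)), function(i)
        list(id = fr$model$sites$id[i],
             pkint = fr$model$sites$pkint[i],
             polarity = fr$model$sites$polarity[i])),
      w = wlist), auto_unbox = TRUE, digits = NA)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read per-frame titration models from JSON-lines
#'
#' Validates every line; parse errors carry the line number. The ensemble
#' label (`"P"` or `"D"`) is required, triplets must not contradict
#' symmetry (both `(i,j)` and `(j,i)` given with different values), and
#' polarities must be known. An empty file yields an empty list with a
#' warning.
#'
#' @param path JSON-lines file.
#' @return Named list of frame records (see [write_frames()]).
#' @export
read_frames <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    warning("read_frames: '", path, "' contains no frames")
    return(list())
  }
  frames <- lapply(seq_along(lines), function(ln) {
    obj <- tryCatch(
      jsonlite::fromJSON(lines[ln], simplifyVector = FALSE),
      error = function(e) stop("read_frames: line ", ln, ": malformed JSON: ",
                               conditionMessage(e), call. = FALSE))
    fail <- function(...) stop("read_frames: line ", ln, ": ", ...,
                               call. = FALSE)
    for (f in c("frame_id", "ensemble", "sites"))
      if (is.null(obj[[f]])) fail("missing field '", f, "'")
    if (!obj$ensemble %in% c("P", "D"))
      fail("ensemble must be 'P' or 'D', got '", obj$ensemble, "'")
    sites <- do.call(rbind, lapply(obj$sites, function(s) {
      if (is.null(s$id) || is.null(s$pkint) || is.null(s$polarity))
        fail("site missing id/pkint/polarity")
      if (!s$polarity %in% c("anionic", "cationic"))
        fail("unknown polarity '", s$polarity, "'")
      data.frame(id = s$id, pkint = as.numeric(s$pkint),
                 polarity = s$polarity, stringsAsFactors = FALSE)
    }))
    n <- nrow(sites)
    w <- matrix(0, n, n)
    seen <- character(0)
    for (t in obj$w) {
      i <- as.integer(t[[1]]) + 1L; j <- as.integer(t[[2]]) + 1L
      v <- as.numeric(t[[3]])
      if (i < 1L || i > n || j < 1L || j > n || i == j)
        fail("coupling triplet index out of range: (", i - 1L, ",",
             j - 1L, ")")
      key <- paste(min(i, j), max(i, j))
      if (key %in% seen && abs(w[i, j] - v) > 1e-12)
        fail("asymmetric duplicate coupling for sites ", min(i, j) - 1L,
             ",", max(i, j) - 1L)
      seen <- c(seen, key)
      w[i, j] <- v; w[j, i] <- v
    }
    model <- tryCatch(titration_model(sites, w),
                      error = function(e) fail(conditionMessage(e)))
    list(frame_id = obj$frame_id,
         replicate = if (is.null(obj$replicate)) NA else obj$replicate,
         time_ps = if (is.null(obj$time_ps)) NA_real_
                   else as.numeric(obj$time_ps),
         ensemble = obj$ensemble, model = model)
  })
  names(frames) <- vapply(frames, `[[`, "", "frame_id")
  frames
}

fmt6 <- function(x) ifelse(is.na(x), "", sprintf("%.6f", x))

#' Write a titration curve as TSV
#'
#' Columns: `ph`, then one column per site id; 6-decimal floats.
#'
#' @param curve a `titration_curve`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_curve_tsv <- function(curve, path) {
  stopifnot(inherits(curve, "titration_curve"))
  tab <- cbind(ph = curve$grid$points, curve$protonation)
  lines <- c(paste(colnames(tab), collapse = "\t"),
             apply(tab, 1L, function(r) paste(fmt6(r), collapse = "\t")))
  writeLines(lines, path)
  invisible(path)
}

#' Write / read a pKhalf table
#'
#' TSV with columns `system`, `replicate`, `time_ps`, `pkhalf`; an empty
#' `pkhalf` cell means undefined (no 0.5 crossing inside the grid).
#'
#' @param tab data.frame with those columns (`pkhalf` may be `NA`).
#' @param path file path.
#' @return `path` / the table.
#' @export
write_pkhalf_tsv <- function(tab, path) {
  lines <- c("system\treplicate\ttime_ps\tpkhalf",
             sprintf("%s\t%s\t%s\t%s", tab$system, tab$replicate,
                     tab$time_ps, fmt6(tab$pkhalf)))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_pkhalf_tsv
#' @export
read_pkhalf_tsv <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = c(pkhalf = "numeric"))
  tab
}

#' Pipeline configuration
#'
#' Assembles and validates the configuration for [run_pipeline()]. Any
#' element can also come from a YAML file via [read_pipeline_config()].
#'
#' @param frames_P,frames_D JSON-lines frame files (P = target fixed
#'   protonated, D = deprotonated), or in-memory frame lists.
#' @param site target site id (default `"Asp2.50"`).
#' @param grid a [ph_grid()] (default -10..20 step 0.25).
#' @param method `"exact"` or `"mc"` per-frame titration.
#' @param mc_steps,mc_burn_in,pair_move_fraction MC parameters (used when
#'   `method = "mc"`).
#' @param seed integer seed (used by MC titration).
#' @param population `"all"`, `"high"` or `"low"`: optionally restrict to
#'   one pKhalf population.
#' @param split_method,split_threshold passed to
#'   [split_pkhalf_populations()] when `population != "all"`.
#' @param split_apply ensembles the split is applied to (subset of
#'   `c("P", "D")`).
#' @param jackknife `"by-replicate"` (default) or `"thirds"` (contiguous
#'   time-ordered thirds of the retained frames, the choice after
#'   population filtering).
#' @param epsilon Henderson-Hasselbalch protonation clamp boundary.
#' @param out_dir output directory (`NULL` = no files written).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(frames_P, frames_D, site = "Asp2.50",
                            grid = ph_grid(), method = c("exact", "mc"),
                            mc_steps = 1e5, mc_burn_in = NULL,
                            pair_move_fraction = 0.1, seed = 1L,
                            population = c("all", "high", "low"),
                            split_method = "kmeans2",
                            split_threshold = NULL,
                            split_apply = c("P", "D"),
                            jackknife = c("by-replicate", "thirds"),
                            epsilon = 1e-6, out_dir = NULL) {
  structure(list(frames_P = frames_P, frames_D = frames_D, site = site,
                 grid = grid, method = match.arg(method),
                 mc_steps = mc_steps,
                 mc_burn_in = if (is.null(mc_burn_in)) floor(mc_steps / 10)
                              else mc_burn_in,
                 pair_move_fraction = pair_move_fraction,
                 seed = as.integer(seed),
                 population = match.arg(population),
                 split_method = split_method,
                 split_threshold = split_threshold,
                 split_apply = split_apply,
                 jackknife = match.arg(jackknife),
                 epsilon = epsilon, out_dir = out_dir),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Recognized keys mirror the [pipeline_config()] arguments, with the grid
#' given as `ph_min` / `ph_max` / `ph_step`.
#'
#' @param path YAML file.
#' @param ... overrides applied on top of the file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path, ...) {
  y <- yaml::read_yaml(path)
  args <- list(...)
  grid <- ph_grid(if (is.null(y$ph_min)) -10 else y$ph_min,
                  if (is.null(y$ph_max)) 20 else y$ph_max,
                  if (is.null(y$ph_step)) 0.25 else y$ph_step)
  y$ph_min <- y$ph_max <- y$ph_step <- NULL
  y$grid <- grid
  y[names(args)] <- args
  do.call(pipeline_config, y)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage [", name, "]: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full ensemble-pKa pipeline
#'
#' Executes per-frame titration, pKhalf extraction, optional pKhalf
#' population splitting, protonation pooling, the Henderson-Hasselbalch
#' transform, the two-endpoint LRA average, the y = x intersection and
#' jackknife resampling. With `out_dir` set, writes the LRA curves TSV
#' (`ph`, `pka_P`, `pka_D`, `pka_LRA`), the pKhalf table, a JSON report
#' and a run log.
#'
#' @param config a [pipeline_config()].
#' @return An object of class `lra_result`: `pka_macro`, `ph_star`, `se`,
#'   `leave_one_out`, `boundary_flag`, `multiple`, `n_frames_P`,
#'   `n_frames_D`, `population`, `pkhalf_table`, `curves` (the three
#'   `ensemble_curve`s) and `split` (when population filtering ran).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  log_lines <- character(0)
  note <- function(...) {
    log_lines <<- c(log_lines, paste0(...))
    invisible(NULL)
  }
  note("protolra ", as.character(utils::packageVersion("protolra")),
       " (R ", getRversion(), "), seed=", config$seed,
       ", method=", config$method, ", site=", config$site)

  frames <- stage("read", {
    get_frames <- function(x, lab) {
      fr <- if (is.character(x)) read_frames(x) else x
      if (!length(fr)) stop("no frames for ensemble ", lab)
      bad <- vapply(fr, function(f) f$ensemble != lab, TRUE)
      if (any(bad)) stop(sum(bad), " frame(s) not labelled '", lab, "'")
      fr
    }
    list(P = get_frames(config$frames_P, "P"),
         D = get_frames(config$frames_D, "D"))
  })
  note("frames: P=", length(frames$P), " D=", length(frames$D))

  curves <- stage("titrate", {
    titrate_one <- function(fr, chain_seed) {
      if (config$method == "exact") exact_titration(fr$model, config$grid)
      else mc_titration(fr$model, config$grid, steps = config$mc_steps,
                        burn_in = config$mc_burn_in,
                        pair_move_fraction = config$pair_move_fraction,
                        seed = chain_seed)
    }
    lapply(c("P", "D"), function(lab) {
      fs <- frames[[lab]]
      # per-frame seeds derived deterministically from the run seed
      lapply(seq_along(fs), function(i)
        titrate_one(fs[[i]],
                    (config$seed + 7919L * i +
                       as.integer(lab == "D")) %% .Machine$integer.max))
    }) |> stats::setNames(c("P", "D"))
  })

  pkh <- stage("pkhalf", {
    tab <- do.call(rbind, lapply(c("P", "D"), function(lab) {
      fs <- frames[[lab]]
      vals <- vapply(curves[[lab]],
                     function(cv) pkhalf(cv, config$site)$value, numeric(1))
      data.frame(system = lab,
                 frame_id = vapply(fs, `[[`, "", "frame_id"),
                 replicate = vapply(fs, function(f)
                   as.character(f$replicate), ""),
                 time_ps = vapply(fs, function(f)
                   as.numeric(f$time_ps), numeric(1)),
                 pkhalf = vals, stringsAsFactors = FALSE)
    }))
    rownames(tab) <- NULL
    tab
  })
  note("pkhalf: ", sum(is.na(pkh$pkhalf)), " undefined of ", nrow(pkh))

  split_info <- NULL
  keep <- stats::setNames(rep(TRUE, nrow(pkh)), pkh$frame_id)
  if (config$population != "all") {
    split_info <- stage("split", {
      sel <- pkh$system %in% config$split_apply
      recs <- data.frame(frame_id = pkh$frame_id[sel],
                         replicate_id = pkh$replicate[sel],
                         time_ps = pkh$time_ps[sel],
                         pkhalf = pkh$pkhalf[sel],
                         stringsAsFactors = FALSE)
      split_pkhalf_populations(recs, method = config$split_method,
                               fixed_threshold = config$split_threshold)
    })
    retained <- if (config$population == "high") split_info$high_frames
                else split_info$low_frames
    dropped <- setdiff(pkh$frame_id[pkh$system %in% config$split_apply],
                       retained)
    keep[dropped] <- FALSE
    note("split: retained ", sum(keep), " of ", nrow(pkh),
         " frames (population=", config$population, ", threshold=",
         sprintf("%.3f", split_info$threshold), ")")
  }

  # estimator over a set of (curve, meta) pairs per ensemble
  estimate <- function(sub_P, sub_D) {
    cp <- hh_transform(pool_protonation(sub_P, config$site),
                       epsilon = config$epsilon, label = "P")
    cd <- hh_transform(pool_protonation(sub_D, config$site),
                       epsilon = config$epsilon, label = "D")
    list(P = cp, D = cd, LRA = lra_average(cp, cd))
  }

  kept_idx <- function(lab) {
    ids <- vapply(frames[[lab]], `[[`, "", "frame_id")
    which(keep[ids])
  }
  idx <- list(P = kept_idx("P"), D = kept_idx("D"))
  result <- stage("lra", {
    est <- estimate(curves$P[idx$P], curves$D[idx$D])
    c(macroscopic_pka(est$LRA), list(curves = est))
  })
  note(sprintf("lra: pka_macro=%.4f (boundary=%s)", result$pka_macro,
               result$boundary_flag))

  jk <- stage("jackknife", {
    partition_of <- function(lab) {
      fs <- frames[[lab]][idx[[lab]]]
      if (config$jackknife == "by-replicate") {
        reps <- vapply(fs, function(f) as.character(f$replicate), "")
        split(seq_along(fs), reps)
      } else {
        ord <- order(vapply(fs, function(f) as.character(f$replicate), ""),
                     vapply(fs, function(f) as.numeric(f$time_ps),
                            numeric(1)))
        thirds <- cut(seq_along(ord), 3L, labels = c("1", "2", "3"))
        split(ord, thirds)
      }
    }
    parts <- list(P = partition_of("P"), D = partition_of("D"))
    pnames <- names(parts$P)
    if (!identical(sort(pnames), sort(names(parts$D))))
      stop("P and D partitions do not align (", length(parts$P), " vs ",
           length(parts$D), ")")
    if (length(pnames) < 2L) stop("need >= 2 partitions for the jackknife")
    theta <- vapply(pnames, function(nm) {
      ip <- unlist(parts$P[setdiff(pnames, nm)], use.names = FALSE)
      id <- unlist(parts$D[setdiff(pnames, nm)], use.names = FALSE)
      est <- estimate(curves$P[idx$P][ip], curves$D[idx$D][id])
      macroscopic_pka(est$LRA)$pka_macro
    }, numeric(1))
    n <- length(theta)
    list(se = sqrt((n - 1) / n * sum((theta - mean(theta))^2)),
         leave_one_out = data.frame(partition = pnames, pka = unname(theta),
                                    stringsAsFactors = FALSE))
  })
  note(sprintf("jackknife: se=%.4f over %d partitions", jk$se,
               nrow(jk$leave_one_out)))

  out <- structure(list(
    pka_macro = result$pka_macro, ph_star = result$ph_star,
    se = jk$se, leave_one_out = jk$leave_one_out,
    boundary_flag = result$boundary_flag, multiple = result$multiple,
    n_frames_P = length(idx$P), n_frames_D = length(idx$D),
    n_frames_total = length(frames$P) + length(frames$D),
    population = config$population, split = split_info,
    pkhalf_table = pkh, curves = result$curves,
    seed = config$seed, log = log_lines), class = "lra_result")

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_lra_outputs(out, config$out_dir)
  }
  out
}

#' @export
print.lra_result <- function(x, ...) {
  cat(sprintf(
    "<lra_result> pKa = %.3f +/- %.3f (pH* = %.3f, %d P + %d D frames%s)\n",
    x$pka_macro, x$se, x$ph_star, x$n_frames_P, x$n_frames_D,
    if (x$population == "all") ""
    else paste0(", population=", x$population)))
  invisible(x)
}

write_lra_outputs <- function(result, out_dir) {
  grid <- result$curves$P$grid
  tab <- data.frame(ph = grid$points,
                    pka_P = result$curves$P$pka_values,
                    pka_D = result$curves$D$pka_values,
                    pka_LRA = result$curves$LRA$pka_values)
  writeLines(c("ph\tpka_P\tpka_D\tpka_LRA",
               apply(tab, 1L, function(r) paste(fmt6(r), collapse = "\t"))),
             file.path(out_dir, "lra_curves.tsv"))
  write_pkhalf_tsv(result$pkhalf_table, file.path(out_dir, "pkhalf.tsv"))
  report <- list(pka_macro = result$pka_macro, ph_star = result$ph_star,
                 se = result$se,
                 leave_one_out = result$leave_one_out,
                 n_frames_P = result$n_frames_P,
                 n_frames_D = result$n_frames_D,
                 n_frames_total = result$n_frames_total,
                 population = result$population,
                 flags = list(boundary = result$boundary_flag,
                              multiple = result$multiple,
                              population_filtered =
                                !is.null(result$split)),
                 seed = result$seed)
  writeLines(jsonlite::toJSON(report, auto_unbox = TRUE, digits = NA,
                              dataframe = "rows"),
             file.path(out_dir, "lra_report.json"))
  writeLines(result$log, file.path(out_dir, "run.log"))
  invisible(out_dir)
}
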