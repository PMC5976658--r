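#' Write an EMG dataset to a directory of plain-text files
#'
#' Layout: `emg.tsv` (long format, columns `trial`, `bin`, then one column
#' per muscle), `labels.tsv` (the per-trial label table) and
#' `manifest.json` (`T`, `M`, `L` and any extra metadata). Values are
#' written with full double precision so a round trip is exact to at least
#' 12 significant digits.
#'
#' @param data an [emg_dataset()].
#' @param path output directory (created if missing).
#' @param extra named list merged into the manifest (e.g. seed, noise sd).
#' @return `path`, invisibly.
#' @export
write_dataset <- function(data, path, extra = list()) {
  stopifnot(inherits(data, "emg_dataset"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  mat <- do.call(rbind, data$trials)
  colnames(mat) <- sprintf("m%02d", seq_len(data$M))
  long <- data.frame(trial = rep(seq_len(data$L), each = data$T_bins),
                     bin = rep(seq_len(data$T_bins), times = data$L))
  long <- cbind(long, format(mat, digits = 17, trim = TRUE, scientific = TRUE))
  write.table(long, file.path(path, "emg.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(data$labels, file.path(path, "labels.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  manifest <- c(list(T = data$T_bins, M = data$M, L = data$L), extra)
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read an EMG dataset written by [write_dataset()]
#'
#' @param path dataset directory; must contain `manifest.json`, `emg.tsv`
#'   and `labels.tsv`. Shape mismatches between the manifest and the data
#'   are rejected with a diagnostic rather than silently misread.
#' @return an [emg_dataset()]; the manifest is attached as attribute
#'   `"manifest"`.
#' @export
read_dataset <- function(path) {
  man_path <- file.path(path, "manifest.json")
  if (!file.exists(man_path)) stop("no manifest.json in ", path)
  man <- jsonlite::read_json(man_path, simplifyVector = TRUE)
  long <- read.delim(file.path(path, "emg.tsv"), check.names = FALSE)
  labels <- read.delim(file.path(path, "labels.tsv"), check.names = FALSE)
  need <- c("trial", "bin")
  if (!all(need %in% names(long))) stop("emg.tsv is missing trial/bin columns")
  Tb <- as.integer(man$T); M <- as.integer(man$M); L <- as.integer(man$L)
  if (nrow(long) != Tb * L || ncol(long) - 2L != M) {
    stop(sprintf("emg.tsv shape (%d rows x %d muscles) does not match manifest (T=%d, M=%d, L=%d)",
                 nrow(long), ncol(long) - 2L, Tb, M, L))
  }
  if (nrow(labels) != L) stop("labels.tsv row count does not match manifest L")
  vals <- as.matrix(long[, -(1:2), drop = FALSE])
  trials <- lapply(seq_len(L), function(l) {
    tr <- vals[long$trial == l, , drop = FALSE]
    if (nrow(tr) != Tb) stop("trial ", l, " has ", nrow(tr), " rows, expected ", Tb)
    dimnames(tr) <- NULL
    tr
  })
  out <- emg_dataset(trials, labels)
  attr(out, "manifest") <- man
  out
}

#' Write / read a fitted space-by-time model
#'
#' Layout: `Wt.tsv` (T x K), `Ws.tsv` (N x M), `A.tsv` (long format:
#' `trial`, `i`, `j`, `value`) and `manifest.json` (K, N, seed, objective).
#'
#' @param model an `sbt_model`.
#' @param path directory.
#' @return `path` invisibly / the `sbt_model`.
#' @export
write_model <- function(model, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  wt <- format(model$Wt, digits = 17, trim = TRUE, scientific = TRUE)
  ws <- format(model$Ws, digits = 17, trim = TRUE, scientific = TRUE)
  write.table(wt, file.path(path, "Wt.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  write.table(ws, file.path(path, "Ws.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  d <- dim(model$A)
  long <- data.frame(trial = rep(seq_len(d[1]), times = d[2] * d[3]),
                     i = rep(rep(seq_len(d[2]), each = d[1]), times = d[3]),
                     j = rep(seq_len(d[3]), each = d[1] * d[2]),
                     value = format(as.vector(model$A), digits = 17,
                                    trim = TRUE, scientific = TRUE))
  write.table(long, file.path(path, "A.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  jsonlite::write_json(list(K = model$K, N = model$N, seed = model$seed,
                            objective = model$objective,
                            restarts = model$restarts,
                            converged = model$converged),
                       file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  man <- jsonlite::read_json(file.path(path, "manifest.json"),
                             simplifyVector = TRUE)
  Wt <- as.matrix(read.delim(file.path(path, "Wt.tsv"), header = FALSE))
  Ws <- as.matrix(read.delim(file.path(path, "Ws.tsv"), header = FALSE))
  dimnames(Wt) <- dimnames(Ws) <- NULL
  long <- read.delim(file.path(path, "A.tsv"))
  K <- as.integer(man$K); N <- as.integer(man$N)
  if (ncol(Wt) != K || nrow(Ws) != N) {
    stop("model factor shapes do not match manifest (K, N)")
  }
  L <- max(long$trial)
  A <- array(0, dim = c(L, K, N))
  A[cbind(long$trial, long$i, long$j)] <- long$value
  structure(list(Wt = Wt, Ws = Ws, A = A, K = K, N = N,
                 objective = man$objective, seed = man$seed,
                 restarts = man$restarts, converged = man$converged,
                 trace = NULL, iterations = NA_integer_),
            class = "sbt_model")
}

#' Default pipeline configuration
#'
#' @param ... overrides of the defaults (unknown names are rejected).
#' @return named list of class `pipeline_config`. Defaults follow the
#'   reference protocol where feasible (50 restarts, 30 repetitions,
#'   permutation count 200, cutoffs 0.5/0.6) and can be scaled down for
#'   quick runs.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    seed = 1L,
    subjects = 1L,
    reps_per_movement = 30L,
    K = 4L, N = 5L,
    select_order = FALSE, Kmax = 10L, Nmax = 10L,
    alpha = 0.05, n_perm = 200L,
    restarts = 50L, tol = 1e-8, max_iter = 500L,
    emg_noise_sd = 0.05, coefficient_noise_sigma = 0.2,
    cutoff_temporal = 0.5, cutoff_spatial = 0.6,
    input = NULL,           # path to an existing dataset; NULL => simulate
    out = NULL              # output directory; NULL => nothing persisted
  )
  ov <- list(...)
  bad <- setdiff(names(ov), names(cfg))
  if (length(bad)) stop("unknown configuration field(s): ",
                        paste(bad, collapse = ", "))
  cfg[names(ov)] <- ov
  structure(cfg, class = "pipeline_config")
}

#' Run the full synergy-analysis pipeline
#'
#' Stages: simulate (or ingest) -> fit (or select the model order) ->
#' per-synergy decoding of all ten task parameters -> bias-corrected task
#' information -> functional-similarity clustering of the synergies (across
#' subjects when `subjects > 1`). Fully deterministic under a fixed
#' configuration: rerunning with the same config reproduces identical
#' summary tables. Stage failures abort with a stage-tagged error.
#'
#' @param config a [pipeline_config()].
#' @return object of class `run_report` with per-stage artifacts: datasets,
#'   fits (`$fits`), the per-synergy decoding/information summary table
#'   (`$summary`), cluster sets (`$clusters_temporal`, `$clusters_spatial`)
#'   and provenance (`$config`, wall times).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    val <- tryCatch(force(expr), error = function(e) {
      stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE)
    })
    list(value = val, wall = proc.time()[["elapsed"]] - t0)
  }
  design <- build_task_design()

  datasets <- stage("simulate", {
    if (!is.null(config$input)) {
      if (!dir.exists(config$input)) {
        stop("input path does not exist: ", config$input)
      }
      list(list(emg = read_dataset(config$input)))
    } else {
      truth <- make_ground_truth(
        config$K, config$N, seed = config$seed,
        coefficient_noise_sigma = config$coefficient_noise_sigma,
        emg_noise_sd = config$emg_noise_sd, design = design)
      synthesize_subjects(truth, config$subjects, design = design,
                          reps_per_movement = config$reps_per_movement,
                          seed = config$seed)
    }
  })

  fits <- stage("fit", lapply(seq_along(datasets$value), function(s) {
    ds <- datasets$value[[s]]$emg
    if (config$select_order) {
      sel <- select_model_order(ds, Kmax = config$Kmax, Nmax = config$Nmax,
                                alpha = config$alpha, n_perm = config$n_perm,
                                restarts = config$restarts,
                                seed = config$seed + s)
      fit_space_by_time(ds, sel$K, sel$N, restarts = config$restarts,
                        tol = config$tol, max_iter = config$max_iter,
                        seed = config$seed + s)
    } else {
      fit_space_by_time(ds, config$K, config$N, restarts = config$restarts,
                        tol = config$tol, max_iter = config$max_iter,
                        seed = config$seed + s)
    }
  }))

  decoding <- stage("decode", {
    params <- task_parameter_names()
    rows <- list()
    confusions <- list()
    for (s in seq_along(fits$value)) {
      model <- fits$value[[s]]$model
      labels <- datasets$value[[s]]$emg$labels
      for (mode in c("temporal", "spatial")) {
        n_syn <- if (mode == "temporal") model$K else model$N
        for (i in seq_len(n_syn)) {
          X <- synergy_features(model, i, mode)
          for (p in params) {
            res <- decode_loocv(X, labels[[p]])
            info <- pt_corrected_information(res$confusion$counts)
            rows[[length(rows) + 1L]] <- data.frame(
              subject = s, mode = mode, synergy = i, parameter = p,
              V = length(res$confusion$class_labels),
              percent_correct = res$percent_correct,
              bits = info$corrected_bits,
              percent_of_max = info$percent_of_max)
            if (p == "movement") {
              confusions[[length(confusions) + 1L]] <- list(
                subject = s, mode = mode, synergy = i,
                result = res)
            }
          }
        }
      }
    }
    list(summary = do.call(rbind, rows), confusions = confusions)
  })

  clusters <- stage("cluster", {
    out <- list()
    for (mode in c("temporal", "spatial")) {
      sel <- Filter(function(cf) cf$mode == mode, decoding$value$confusions)
      if (length(sel) < 2) {
        out[[mode]] <- NULL
        next
      }
      registry <- do.call(rbind, lapply(sel, function(cf)
        data.frame(subject = cf$subject, mode = cf$mode, synergy = cf$synergy)))
      synergies <- lapply(sel, function(cf) {
        m <- fits$value[[cf$subject]]$model
        if (mode == "temporal") m$Wt[, cf$synergy] else m$Ws[cf$synergy, ]
      })
      cutoff <- if (mode == "temporal") config$cutoff_temporal else config$cutoff_spatial
      out[[mode]] <- cluster_synergies(lapply(sel, `[[`, "result"),
                                       cutoff = cutoff, registry = registry,
                                       synergies = synergies)
    }
    out
  })

  report <- structure(list(
    config = config,
    design = design,
    datasets = datasets$value,
    fits = fits$value,
    vaf = vapply(fits$value, `[[`, numeric(1), "vaf"),
    summary = decoding$value$summary,
    confusions = decoding$value$confusions,
    clusters_temporal = clusters$value$temporal,
    clusters_spatial = clusters$value$spatial,
    wall_times = c(simulate = datasets$wall, fit = fits$wall,
                   decode = decoding$wall, cluster = clusters$wall)
  ), class = "run_report")

  if (!is.null(config$out)) {
    dir.create(config$out, recursive = TRUE, showWarnings = FALSE)
    for (s in seq_along(report$datasets)) {
      write_dataset(report$datasets[[s]]$emg,
                    file.path(config$out, sprintf("subject%02d", s)),
                    extra = list(seed = config$seed))
      write_model(report$fits[[s]]$model,
                  file.path(config$out, sprintf("model%02d", s)))
    }
    summ <- report$summary
    summ$percent_correct <- round(summ$percent_correct, 6)
    summ$bits <- round(summ$bits, 6)
    write.table(summ, file.path(config$out, "decoding_summary.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    writeLines(render_report(report), file.path(config$out, "report.txt"))
  }
  report
}

#' Render a pipeline run as a human-readable summary
#'
#' Formats the run in the field's reporting style: VAF and percent correct
#' as integer percentages, information in bits to two decimals.
#'
#' @param report a `run_report` from [run_pipeline()].
#' @return character vector of report lines.
#' @export
render_report <- function(report) {
  stopifnot(inherits(report, "run_report"))
  lines <- c("Space-by-time synergy analysis report",
             sprintf("Subjects: %d; seed %d", length(report$fits),
                     report$config$seed))
  for (s in seq_along(report$fits)) {
    m <- report$fits[[s]]$model
    lines <- c(lines, sprintf("Subject %d: K = %d, N = %d, VAF = %d%%",
                              s, m$K, m$N, round(100 * report$vaf[s])))
  }
  lines <- c(lines, "", "Per-synergy decoding (movement and task parameters):",
             "subject\tmode\tsynergy\tparameter\tpct_correct\tbits\tpct_max")
  sm <- report$summary
  for (i in seq_len(nrow(sm))) {
    lines <- c(lines, sprintf("%d\t%s\t%d\t%s\t%d\t%.2f\t%d",
                              sm$subject[i], sm$mode[i], sm$synergy[i],
                              sm$parameter[i], round(sm$percent_correct[i]),
                              sm$bits[i], sm$percent_of_max[i]))
  }
  for (mode in c("temporal", "spatial")) {
    cl <- report[[paste0("clusters_", mode)]]
    lines <- c(lines, "",
               if (is.null(cl)) {
                 sprintf("Clustering (%s): not run", mode)
               } else {
                 c(sprintf("Clustering (%s, cutoff %.2f): %d cluster(s), %d unclustered",
                           mode, cl$cutoff, cl$n_clusters,
                           sum(is.na(cl$assignments))),
                   vapply(cl$summaries, function(s)
                     sprintf("  C%d: members %s", s$cluster,
                             paste(s$members, collapse = ",")),
                     character(1)))
               })
  }
  lines
}

#' @export
print.run_report <- function(x, ...) {
  cat(render_report(x), sep = "\n")
  invisible(x)
}
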