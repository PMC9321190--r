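# End-to-end analysis: simulate or ingest a cohort, fit every participant,
# apply control-derived cut-offs, summarise groups, relate EWB to EWBr.

# Stable non-cryptographic hash of the run configuration for the manifest.
config_hash <- function(x) {
  s <- as.character(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA,
                                     null = "null"))
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

spec_to_list <- function(spec) {
  if (is.null(spec)) return(NULL)
  list(
    n_per_group = spec$n_per_group,
    seed = spec$seed,
    design = unclass(spec$design),
    control = unclass(spec$control),
    neglect = unclass(spec$neglect)
  )
}

#' Run the full endpoint-weightings analysis
#'
#' Either simulates a cohort from a [cohort_spec()] or ingests trial tables
#' (tibbles, or paths to CSV files in the package schemas), then: fits every
#' participant ([fit_cohort()]); derives upper abnormality cut-offs for mean
#' DBE, EWB and EWBr from the control participants ([neglect_cutoff()]) and
#' flags every participant against them; builds the group summary with
#' standardized effect sizes ([summarize_groups()]); and computes the EWB-EWBr
#' association pooled across groups and for the neglect group alone
#' ([association_r2()]). All outputs are a pure function of the inputs and the
#' spec seed, so reruns are byte-identical.
#'
#' If no control participants are available, the summary is still produced but
#' cut-offs and flags are omitted with a warning.
#'
#' @param spec A [cohort_spec()] to simulate from (exclusive with `bisection`).
#' @param bisection,reproduction Trial tables or CSV paths (exclusive with
#'   `spec`); `reproduction` may be `NULL`.
#' @param alpha One-tailed significance level for the cut-offs.
#' @param apply_correction Use the bias-corrected effect size as the headline
#'   estimate in the group summary.
#' @param method Bisection fit dispatch, see [fit_participant()].
#' @param out_dir If non-`NULL`, write `participants.csv`, `summary.csv`,
#'   `association.json`, `manifest.json` (and, for simulated cohorts,
#'   `bisection.csv` / `reproduction.csv`) into this directory.
#' @return A list of class `neglect_pipeline`: `participants` (fit table with
#'   flag columns), `cutoffs` (tibble of measure, cutoff, alpha), `summary`,
#'   `association` (list with `pooled` and `neglect_only`), `manifest`, and
#'   `data` (the trial tables analysed).
#' @export
#' @examples
#' res <- run_pipeline(spec = default_cohort_spec(seed = 1))
#' res$summary
#' res$association$pooled
run_pipeline <- function(spec = NULL, bisection = NULL, reproduction = NULL,
                         alpha = 0.05, apply_correction = TRUE,
                         method = "auto", out_dir = NULL) {
  if (is.null(spec) == is.null(bisection)) {
    stop_nw("nw_spec_error",
            "supply exactly one of `spec` or `bisection` (+ `reproduction`)")
  }
  simulated <- !is.null(spec)
  if (simulated) {
    cohort <- generate_cohort(spec)
    bisection <- cohort$bisection
    reproduction <- cohort$reproduction
  } else {
    if (is.character(bisection)) bisection <- read_bisection_csv(bisection)
    if (is.character(reproduction)) {
      reproduction <- read_reproduction_csv(reproduction)
    }
    bisection <- validate_bisection_trials(bisection)
    if (!is.null(reproduction)) {
      reproduction <- validate_reproduction_trials(reproduction)
    }
  }

  fits <- fit_cohort(bisection, reproduction, method = method)

  measures <- c(DBE = "mean_dbe_mm", EWB = "ewb", EWBr = "ewbr")
  cutoffs <- NULL
  for (i in seq_along(measures)) {
    col <- measures[[i]]
    ctl <- fits[[col]][fits$group == "control"]
    ctl <- ctl[is.finite(ctl)]
    if (length(ctl) >= 2 && sd(ctl) > 0) {
      cut <- neglect_cutoff(ctl, alpha = alpha, tail = "upper")
      cutoffs <- dplyr::bind_rows(cutoffs, tibble(
        measure = names(measures)[i], cutoff = cut, alpha = alpha,
        n_controls = length(ctl)
      ))
      fits[[paste0("flag_", tolower(names(measures)[i]))]] <-
        ifelse(is.finite(fits[[col]]), fits[[col]] > cut, NA)
    }
  }
  if (is.null(cutoffs)) {
    warning("no usable control sample: cut-offs and abnormality flags omitted",
            call. = FALSE)
  }

  summary <- summarize_groups(fits, measures = measures,
                              apply_correction = apply_correction)

  safe_assoc <- function(x, y) {
    tryCatch(association_r2(x, y), neglectweights_error = function(e) NULL)
  }
  neg <- fits$group == "neglect"
  association <- list(
    pooled = safe_assoc(fits$ewb, fits$ewbr),
    neglect_only = safe_assoc(fits$ewb[neg], fits$ewbr[neg])
  )

  config <- list(
    source = if (simulated) "simulated" else "supplied",
    spec = spec_to_list(spec), alpha = alpha,
    apply_correction = apply_correction, method = method
  )
  manifest <- list(
    package = "neglectweights",
    version = as.character(packageVersion("neglectweights")),
    seed = if (simulated) spec$seed else NA,
    config = config,
    config_hash = config_hash(config),
    n_participants = nrow(fits),
    n_bisection_trials = nrow(bisection),
    n_reproduction_trials = if (is.null(reproduction)) 0L else nrow(reproduction)
  )

  result <- structure(
    list(participants = fits, cutoffs = cutoffs, summary = summary,
         association = association, manifest = manifest,
         data = list(bisection = bisection, reproduction = reproduction)),
    class = "neglect_pipeline"
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_fits_csv(fits, file.path(out_dir, "participants.csv"))
    readr::write_csv(round6(summary), file.path(out_dir, "summary.csv"),
                     progress = FALSE)
    assoc_out <- lapply(association, function(a) {
      if (is.null(a)) NULL else unclass(a)
    })
    jsonlite::write_json(assoc_out, file.path(out_dir, "association.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         pretty = TRUE)
    if (simulated) {
      write_bisection_csv(bisection, file.path(out_dir, "bisection.csv"))
      write_reproduction_csv(reproduction,
                             file.path(out_dir, "reproduction.csv"))
    }
  }
  result
}

#' @export
print.neglect_pipeline <- function(x, ...) {
  cat(sprintf("<neglect_pipeline> %d participants (%d bisection, %d reproduction trials)\n",
              x$manifest$n_participants, x$manifest$n_bisection_trials,
              x$manifest$n_reproduction_trials))
  cat(format_summary_table(x$summary), sep = "\n")
  if (!is.null(x$association$pooled)) {
    cat(sprintf("EWB-EWBr r^2 (pooled) = %.3f\n",
                x$association$pooled$r_squared))
  }
  invisible(x)
}

#' Write seeded test fixtures
#'
#' Generates two small cohorts — the default length-manipulated design and an
#' independent-endpoint design — with three agents per group, and writes their
#' trial CSVs together with the per-participant fit tables computed by
#' [fit_cohort()]. Deterministic given `seed`.
#'
#' @param seed Integer root seed.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the named vector of file paths written.
#' @export
make_fixtures <- function(seed, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (file.access(out_dir, mode = 2) != 0) {
    stop_nw("nw_io_error", sprintf("cannot write to '%s'", out_dir))
  }
  specs <- list(
    length = cohort_spec(n_per_group = 3L, design = design_spec(
      "length_manipulated", reps_per_condition = 4L), seed = seed),
    independent = cohort_spec(n_per_group = 3L, design = design_spec(
      "independent_endpoints", reps_per_condition = 20L), seed = seed + 1L)
  )
  paths <- character(0)
  for (nm in names(specs)) {
    cohort <- generate_cohort(specs[[nm]])
    p <- c(
      bisection = file.path(out_dir, sprintf("%s_bisection.csv", nm)),
      reproduction = file.path(out_dir, sprintf("%s_reproduction.csv", nm)),
      fits = file.path(out_dir, sprintf("%s_fits.csv", nm))
    )
    write_bisection_csv(cohort$bisection, p[["bisection"]])
    write_reproduction_csv(cohort$reproduction, p[["reproduction"]])
    write_fits_csv(fit_cohort(cohort$bisection, cohort$reproduction),
                   p[["fits"]])
    names(p) <- paste(nm, names(p), sep = "_")
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Scatter the per-participant bias measures
#'
#' Optional reporting aid: mean DBE against EWB, or EWB against EWBr, with the
#' control-derived cut-offs as dotted lines. Requires ggplot2.
#'
#' @param result A `neglect_pipeline` from [run_pipeline()].
#' @param which `"bisection"` (mean DBE vs EWB) or `"tasks"` (EWBr vs EWB).
#' @return A ggplot object.
#' @export
plot_bias <- function(result, which = c("bisection", "tasks")) {
  which <- match.arg(which)
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop_nw("nw_spec_error", "plot_bias() requires the ggplot2 package")
  }
  fits <- result$participants
  cuts <- result$cutoffs
  cut_of <- function(m) {
    if (is.null(cuts)) NA_real_ else {
      v <- cuts$cutoff[cuts$measure == m]
      if (length(v)) v else NA_real_
    }
  }
  if (which == "bisection") {
    xcol <- "mean_dbe_mm"; ycol <- "ewb"
    xcut <- cut_of("DBE"); ycut <- cut_of("EWB")
    labs <- ggplot2::labs(x = "Mean DBE (mm)", y = "EWB")
  } else {
    xcol <- "ewbr"; ycol <- "ewb"
    xcut <- cut_of("EWBr"); ycut <- cut_of("EWB")
    labs <- ggplot2::labs(x = "EWBr", y = "EWB")
  }
  p <- ggplot2::ggplot(fits, ggplot2::aes(
    x = .data[[xcol]], y = .data[[ycol]], colour = .data$group)) +
    ggplot2::geom_point(size = 2) +
    labs +
    ggplot2::theme_minimal()
  if (is.finite(xcut)) p <- p + ggplot2::geom_vline(xintercept = xcut,
                                                    linetype = "dotted")
  if (is.finite(ycut)) p <- p + ggplot2::geom_hline(yintercept = ycut,
                                                    linetype = "dotted")
  p
}
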