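## Results serialization: daily time series and dose responses as CSV, a
## case summary as JSON. Every artifact embeds the resolved parameter set and
## its hash so identical configurations are recognizable.

#' Write the result bundle of a case run
#'
#' @param case_result `vessel_case` from [run_case()].
#' @param out_dir output directory (created if missing).
#' @return invisible character vector of the files written.
#' @export
write_results <- function(case_result, out_dir) {
  stopifnot(inherits(case_result, "vessel_case"))
  ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE,
                                          showWarnings = FALSE)
  if (!ok || !dir.exists(out_dir)) {
    stop("cannot create output directory: ", out_dir, call. = FALSE)
  }
  id <- case_result$case_id
  files <- character(0)

  f <- file.path(out_dir, paste0(id, "_timeseries.csv"))
  utils::write.csv(case_result$history, f, row.names = FALSE)
  files <- c(files, f)

  f <- file.path(out_dir, paste0(id, "_doses.csv"))
  utils::write.csv(case_result$myograph$doses, f, row.names = FALSE)
  files <- c(files, f)

  f <- file.path(out_dir, paste0(id, "_force_displacement.csv"))
  utils::write.csv(case_result$myograph$force_displacement, f,
                   row.names = FALSE)
  files <- c(files, f)

  params <- case_result$vessel$params
  summary <- list(
    case = id,
    clamp_load_N = case_result$load_case,
    healing_days = case_result$healing_days,
    fractions = as.list(case_result$fractions),
    myograph = list(
      preload_gap_mm = case_result$myograph$preload_gap,
      isometric_forces = stats::setNames(
        as.list(case_result$myograph$doses$force),
        case_result$myograph$doses$stage)
    ),
    config_hash = case_result$config_hash,
    parameters = {
      q <- unclass(params); attr(q, "provenance") <- NULL; q
    }
  )
  f <- file.path(out_dir, paste0(id, "_summary.json"))
  jsonlite::write_json(summary, f, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  files <- c(files, f)
  invisible(files)
}
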