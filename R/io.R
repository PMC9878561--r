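## CSV and config round-tripping: the decision-log dialect (UTF-8, header
## row, "." decimal separator, plain integers for points), fit tables in
## the published layout (term, OR, B, SE, z, p), YAML run configs with a
## mandatory seed, and JSON run-metadata sidecars.

DECISION_LOG_COLS <- c("participant_id", "trial_id", "variant", "condition",
                       "framing", "stage", "prior_investments",
                       "responsibility_code", "p_win", "p_tie", "p_lose",
                       "preference", "numeracy", "risk", "decision",
                       "invested", "payout")

#' Write / read a decision-log CSV
#'
#' @param data Decision table (see [simulate_experiment()] for the column
#'   dialect).
#' @param path File path.
#' @return `write_decision_log()` returns `path` invisibly;
#'   `read_decision_log()` the data frame.
#' @export
write_decision_log <- function(data, path) {
    d <- as.data.frame(data)
    missing_cols <- setdiff(DECISION_LOG_COLS, names(d))
    if (length(missing_cols)) {
        stop("decision log is missing column(s): ",
             paste(missing_cols, collapse = ", "))
    }
    d <- d[DECISION_LOG_COLS]
    for (cc in c("p_win", "p_tie", "p_lose", "numeracy", "risk")) {
        d[[cc]] <- format(d[[cc]], digits = 17, trim = TRUE,
                          scientific = FALSE)
    }
    write.csv(d, path, row.names = FALSE, quote = FALSE,
              fileEncoding = "UTF-8", na = "")
    invisible(path)
}

#' @rdname write_decision_log
#' @export
read_decision_log <- function(path) {
    d <- read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8",
                  na.strings = "")
    missing_cols <- setdiff(DECISION_LOG_COLS, names(d))
    if (length(missing_cols)) {
        stop("not a decision log (missing ",
             paste(missing_cols, collapse = ", "), "): ", path)
    }
    int_cols <- c("stage", "prior_investments", "preference", "decision")
    for (cc in int_cols) d[[cc]] <- as.integer(d[[cc]])
    chr_cols <- c("variant", "condition", "framing", "responsibility_code")
    for (cc in chr_cols) d[[cc]] <- as.character(d[[cc]])
    d
}

#' Export a fit as a CSV in the published table layout
#'
#' Columns `term`, `OR`, `B`, `SE`, `z`, `p` (for a linear fit the `z`
#' column holds t statistics and `OR` is empty), followed by one
#' `s2_<group>` row block encoded in a trailing comment-free form: the
#' random-effect variances are appended as rows with term `s2(<group>)`
#' and the estimate in `B`.
#'
#' @param fit A `vip_fit`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_fit_table <- function(fit, path) {
    stopifnot(inherits(fit, "vip_fit"))
    tab <- fit$coefficients
    out <- data.frame(term = tab$term, OR = tab$or, B = tab$estimate,
                      SE = tab$se, z = tab$z, p = tab$p,
                      stringsAsFactors = FALSE)
    s2 <- data.frame(term = sprintf("s2(%s)", names(fit$s2)), OR = NA,
                     B = unname(fit$s2), SE = NA, z = NA, p = NA)
    write.csv(rbind(out, s2), path, row.names = FALSE, na = "")
    invisible(path)
}

RUN_CONFIG_KEYS <- c("variant", "n_participants", "n_trials", "seed",
                     "framing_allocation", "agent", "out")

#' Read / write a run configuration
#'
#' Plain-text (YAML) run configs describe a simulation: `variant`,
#' `n_participants`, `n_trials`, mandatory `seed`, optional
#' `framing_allocation`, `agent` (named coefficient overrides for
#' [agent_params()]), and `out`. Unknown keys are rejected.
#'
#' @param path File path.
#' @param config Named list of config values.
#' @return `read_run_config()` returns the validated list.
#' @export
read_run_config <- function(path) {
    cfg <- yaml::read_yaml(path)
    unknown <- setdiff(names(cfg), RUN_CONFIG_KEYS)
    if (length(unknown)) {
        stop("unknown config key(s): ", paste(unknown, collapse = ", "))
    }
    if (is.null(cfg$seed)) stop("config must set a seed")
    if (is.null(cfg$variant)) stop("config must set a variant")
    cfg
}

#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
    unknown <- setdiff(names(config), RUN_CONFIG_KEYS)
    if (length(unknown)) {
        stop("unknown config key(s): ", paste(unknown, collapse = ", "))
    }
    yaml::write_yaml(config, path)
    invisible(path)
}

# JSON sidecar recording how an output file was produced
write_run_metadata <- function(out_path, seed, config) {
    meta <- list(seed = seed,
                 package = "viptask",
                 version = as.character(packageVersion("viptask")),
                 config = config)
    jsonlite::write_json(meta, paste0(out_path, ".meta.json"),
                         auto_unbox = TRUE, pretty = TRUE, null = "null")
    invisible(meta)
}
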