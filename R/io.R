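## File formats: contour-table CSV, feature-table CSV, YAML run
## configuration, results JSON, and the thin command-line dispatcher.

.CSV_META_COLS <- c("token_id", "speaker_id", "seq_id", "gender", "tone",
                    "position", "prev_tone", "scale", "duration_s", "split")

#' Write a corpus to a contour-table CSV
#'
#' One row per token, sorted by `token_id`: the metadata columns of
#' [ToneCorpus-class] followed by the sample columns `v01..v30`.  Numeric
#' fields are written at full double precision, so write/read round-trips
#' are lossless and repeated writes are byte-identical.
#'
#' @param corpus a [ToneCorpus-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeContourTable <- function(corpus, path) {
    stopifnot(methods::is(corpus, "ToneCorpus"))
    cd <- as.data.frame(SummarizedExperiment::colData(corpus))
    f0 <- t(f0Samples(corpus))
    n_pts <- ncol(f0)
    df <- cbind(cd[, .CSV_META_COLS, drop = FALSE],
                as.data.frame(f0, optional = TRUE))
    colnames(df) <- c(.CSV_META_COLS, sprintf("v%02d", seq_len(n_pts)))
    df <- df[order(df$token_id), , drop = FALSE]
    num <- vapply(df, is.double, logical(1))
    df[num] <- lapply(df[num], function(x) sprintf("%.17g", x))
    con <- file(path, open = "wb")
    on.exit(close(con))
    write.csv(df, con, row.names = FALSE, quote = FALSE, na = "", eol = "\n")
    invisible(path)
}

#' Read a contour-table CSV back into a ToneCorpus
#'
#' Validates the header, the per-row column count, the 30 sample columns
#' and Hz positivity; malformed rows are reported with their line number.
#' Speaker base pitches are not stored in the table, so the reconstructed
#' speaker table carries ids and genders only.
#'
#' @param path CSV file written by [writeContourTable()] (or matching its
#'   schema).
#' @return A [ToneCorpus-class].
#' @export
readContourTable <- function(path) {
    if (!file.exists(path))
        stop("no such file: ", path)
    df <- read.csv(path, stringsAsFactors = FALSE, na.strings = "",
                   check.names = FALSE)
    v_cols <- grep("^v[0-9]{2}$", colnames(df), value = TRUE)
    missing <- setdiff(.CSV_META_COLS, colnames(df))
    if (length(missing))
        stop("contour table misses column(s): ",
             paste(missing, collapse = ", "))
    if (length(v_cols) != 30L)
        stop("expected 30 sample columns v01..v30, found ", length(v_cols))
    for (v in v_cols) {
        x <- suppressWarnings(as.numeric(df[[v]]))
        bad <- which(is.na(x) | !is.finite(x))
        if (length(bad))
            stop("malformed sample value in column ", v, ", file line ",
                 bad[1L] + 1L)
        df[[v]] <- x
    }
    hz_bad <- which(df$scale == "hz" &
                    apply(df[, v_cols] <= 0, 1L, any))
    if (length(hz_bad))
        stop("non-positive Hz sample in file line ", hz_bad[1L] + 1L)
    tokens <- df[, .CSV_META_COLS, drop = FALSE]
    tokens$tone <- as.integer(tokens$tone)
    tokens$position <- as.integer(tokens$position)
    tokens$prev_tone <- as.integer(tokens$prev_tone)
    speakers <- unique(tokens[, c("speaker_id", "gender")])
    rownames(speakers) <- NULL
    ToneCorpus(t(as.matrix(df[, v_cols])), tokens, speakers = speakers)
}

#' Write a per-token feature table to CSV
#'
#' One row per token: `token_id`, `scheme_id`, the feature values
#' `v1..vK`, and the true tone.
#'
#' @param features numeric matrix from [featureMatrix()] (rownames =
#'   token ids).
#' @param tones integer tone labels, one per row.
#' @param scheme_id identifier recorded in every row.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeFeatureTable <- function(features, tones, scheme_id, path) {
    stopifnot(is.matrix(features), nrow(features) == length(tones))
    df <- data.frame(token_id = rownames(features), scheme_id = scheme_id)
    vals <- as.data.frame(features, optional = TRUE)
    colnames(vals) <- sprintf("v%d", seq_len(ncol(features)))
    df <- cbind(df, lapply(vals, function(x) sprintf("%.17g", x)),
                tone = as.integer(tones))
    df <- df[order(df$token_id), , drop = FALSE]
    con <- file(path, open = "wb")
    on.exit(close(con))
    write.csv(df, con, row.names = FALSE, quote = FALSE, eol = "\n")
    invisible(path)
}

## ---- run configuration --------------------------------------------------

.defaultRunConfig <- function() {
    list(seed = 1L,
         corpus = unclass(corpusConfig())[setdiff(names(corpusConfig()),
                                                  "tone_targets")],
         tone_targets = defaultToneTargets(),
         split = list(train_parts = 2L, test_parts = 1L),
         svm = list(cost = 2^seq(-1, 7, by = 2),
                    gamma = 2^seq(-7, 1, by = 2), folds = 5L,
                    tune_max_n = Inf, scale_features = FALSE),
         som = unclass(somSpec()),
         run = list(include_hz = FALSE, include_som = FALSE))
}

.mergeConfig <- function(defaults, user, path = "") {
    if (is.null(user))
        return(defaults)
    if (!is.list(user))
        stop("config section '", path, "' must be a mapping")
    unknown <- setdiff(names(user), names(defaults))
    if (length(unknown))
        stop("unknown config key(s): ",
             paste(paste0(path, unknown), collapse = ", "))
    for (k in names(user)) {
        if (is.list(defaults[[k]]) && !is.null(names(defaults[[k]])))
            defaults[[k]] <- .mergeConfig(defaults[[k]], user[[k]],
                                          paste0(path, k, "."))
        else
            defaults[[k]] <- user[[k]]
    }
    defaults
}

#' Load a YAML run configuration
#'
#' Reads a (possibly empty) YAML file, merges it over the package
#' defaults, and rejects unknown keys by name.  The resolved configuration
#' — with every seed and default made explicit — is returned; set
#' `echo = TRUE` to also print it.
#'
#' @param path YAML file; missing or empty files yield the defaults.
#' @param echo print the resolved configuration to stderr.
#' @return Named list with sections `seed`, `corpus`, `tone_targets`,
#'   `split`, `svm`, `som`, `run`.
#' @export
loadRunConfig <- function(path = NULL, echo = FALSE) {
    defaults <- .defaultRunConfig()
    user <- if (!is.null(path) && file.exists(path))
        yaml::read_yaml(path) else NULL
    cfg <- .mergeConfig(defaults, user)
    if (!is.null(user$tone_targets)) {
        tt <- matrix(unlist(user$tone_targets), ncol = 2L, byrow = TRUE,
                     dimnames = list(paste0("T", 1:4), c("m", "b")))
        cfg$tone_targets <- tt
    }
    if (echo)
        message(yaml::as.yaml(.configAsList(cfg)))
    cfg
}

.configAsList <- function(cfg) {
    cfg$tone_targets <- lapply(seq_len(nrow(cfg$tone_targets)),
                               function(i) unname(cfg$tone_targets[i, ]))
    cfg
}

#' Build a corpusConfig from a loaded run configuration
#'
#' @param cfg list from [loadRunConfig()].
#' @return A [corpusConfig()].
#' @export
configToCorpusConfig <- function(cfg) {
    do.call(corpusConfig, c(cfg$corpus, list(tone_targets = cfg$tone_targets)))
}

## ---- results JSON -------------------------------------------------------

#' Serialize a RecognitionResult to a plain list / JSON file
#'
#' The list (and the JSON written from it) contains the scheme
#' configuration, split sizes, accuracies, the 5-outcome confusion rows,
#' chosen hyperparameters, the seed and the complexity entry — everything
#' needed to reproduce or re-score the run.
#'
#' @param result a [RecognitionResult-class].
#' @param path optional output path; when given, pretty JSON is written.
#' @return The list (invisibly when `path` is given).
#' @export
resultToList <- function(result, path = NULL) {
    stopifnot(methods::is(result, "RecognitionResult"))
    x <- list(scheme = result@scheme, scale = result@scale,
              recognizer = result@recognizer, mode = result@mode,
              cue_pair = result@cue_pair,
              include_onset = result@include_onset,
              seed = result@seed, n_train = result@n_train,
              n_test = result@n_test, accuracy_pct = result@accuracy_pct,
              macro_accuracy_pct = result@macro_accuracy_pct,
              per_tone_accuracy_pct = as.list(result@per_tone_accuracy_pct),
              confusion = apply(result@confusion, 1L, as.list,
                                simplify = FALSE),
              hyperparameters = result@hyperparameters,
              complexity = result@complexity)
    if (!is.null(path)) {
        jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                             pretty = TRUE, na = "null")
        return(invisible(x))
    }
    x
}

## ---- command line -------------------------------------------------------

.cliUsage <- function() {
    paste(
        "usage: tone-pipeline.R <subcommand> [options]",
        "",
        "subcommands:",
        "  synth      --seed N [--config FILE] --out PREFIX",
        "             build + split a synthetic corpus; writes",
        "             PREFIX_contours.csv and PREFIX_meta.json",
        "  features   --scheme S [--scale SC] [--cue-pair P] [--onset]",
        "             --corpus FILE --out FILE.csv",
        "  run        --scheme S [--scale SC] [--recognizer R] [--mode M]",
        "             [--cue-pair P] [--onset] [--seed N] --corpus FILE",
        "             --out FILE.json",
        "  run-all    [--seed N] [--hz] [--som] --corpus FILE --out DIR",
        "  complexity [--out FILE.json]",
        sep = "\n")
}

.cliParse <- function(args) {
    flags <- list()
    i <- 1L
    while (i <= length(args)) {
        a <- args[i]
        if (!startsWith(a, "--"))
            stop("unexpected argument '", a, "'\n", .cliUsage())
        key <- substring(a, 3L)
        if (key %in% c("onset", "hz", "som")) {
            flags[[key]] <- TRUE
            i <- i + 1L
        } else {
            if (i == length(args))
                stop("flag --", key, " needs a value\n", .cliUsage())
            flags[[key]] <- args[i + 1L]
            i <- i + 2L
        }
    }
    flags
}

.cliNeed <- function(flags, key) {
    if (is.null(flags[[key]]))
        stop("missing required flag --", key, "\n", .cliUsage())
    flags[[key]]
}

.cliCheckFlags <- function(flags, allowed) {
    unknown <- setdiff(names(flags), allowed)
    if (length(unknown))
        stop("unknown flag(s): ", paste0("--", unknown, collapse = ", "),
             "\n", .cliUsage())
}

.cliLoadSplitCorpus <- function(flags) {
    corpus <- readContourTable(.cliNeed(flags, "corpus"))
    if (any(is.na(corpusSplit(corpus))))
        corpus <- splitCorpus(corpus,
                              seed = as.integer(flags$seed %||% 1L))
    corpus
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Command-line dispatcher for the tone-recognition pipeline
#'
#' Thin wrapper over the package functions, invoked by
#' `inst/scripts/tone-pipeline.R`.  Subcommands: `synth` (build, split and
#' write a corpus), `features` (write one scheme's feature table), `run`
#' (one scheme end to end, results as JSON), `run-all` (the summary
#' roster), `complexity` (the ledger).  Returns the exit status instead of
#' quitting so it can be driven programmatically.
#'
#' @param args character vector of command-line arguments.
#' @return Integer exit status (0 on success), invisibly.
#' @export
toneCli <- function(args = commandArgs(trailingOnly = TRUE)) {
    status <- tryCatch({
        if (!length(args)) {
            message(.cliUsage())
            return(invisible(1L))
        }
        cmd <- args[1L]
        flags <- .cliParse(args[-1L])
        switch(cmd,
            synth = {
                .cliCheckFlags(flags, c("seed", "config", "out"))
                cfg <- loadRunConfig(flags$config)
                seed <- as.integer(flags$seed %||% cfg$seed)
                prefix <- .cliNeed(flags, "out")
                corpus <- buildCorpus(configToCorpusConfig(cfg), seed = seed)
                corpus <- splitCorpus(corpus,
                                      ratio = c(cfg$split$train_parts,
                                                cfg$split$test_parts),
                                      seed = seed)
                writeContourTable(corpus, paste0(prefix, "_contours.csv"))
                jsonlite::write_json(
                    list(seed = seed, n_tokens = ncol(corpus),
                         tone_counts = as.list(tabulate(toneLabels(corpus),
                                                        4L)),
                         config = .configAsList(cfg)),
                    paste0(prefix, "_meta.json"), auto_unbox = TRUE,
                    digits = NA, pretty = TRUE)
                message("wrote ", prefix, "_contours.csv (",
                        ncol(corpus), " tokens)")
            },
            features = {
                .cliCheckFlags(flags, c("scheme", "scale", "cue-pair",
                                        "onset", "corpus", "out"))
                corpus <- readContourTable(.cliNeed(flags, "corpus"))
                scheme <- .cliNeed(flags, "scheme")
                feats <- featureMatrix(
                    corpus, scheme, scale = flags$scale %||% "semitone",
                    cue_pair = flags[["cue-pair"]] %||% "slope+curve",
                    include_onset = isTRUE(flags$onset))
                writeFeatureTable(feats, toneLabels(corpus), scheme,
                                  .cliNeed(flags, "out"))
            },
            run = {
                .cliCheckFlags(flags, c("scheme", "scale", "recognizer",
                                        "mode", "cue-pair", "onset", "seed",
                                        "corpus", "out"))
                corpus <- .cliLoadSplitCorpus(flags)
                res <- runScheme(
                    corpus, scheme = .cliNeed(flags, "scheme"),
                    scale = flags$scale %||% "semitone",
                    recognizer = flags$recognizer %||% "svm",
                    mode = flags$mode %||% "separate",
                    cue_pair = flags[["cue-pair"]] %||% "slope+curve",
                    include_onset = isTRUE(flags$onset),
                    seed = as.integer(flags$seed %||% 1L))
                resultToList(res, .cliNeed(flags, "out"))
                message(sprintf("%s: %.2f%%", res@scheme, res@accuracy_pct))
            },
            `run-all` = {
                .cliCheckFlags(flags, c("seed", "hz", "som", "corpus",
                                        "out"))
                corpus <- .cliLoadSplitCorpus(flags)
                out_dir <- .cliNeed(flags, "out")
                dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
                all <- runAll(corpus, seed = as.integer(flags$seed %||% 1L),
                              include_hz = isTRUE(flags$hz),
                              include_som = isTRUE(flags$som))
                for (nm in names(all$results))
                    resultToList(all$results[[nm]],
                                 file.path(out_dir, paste0(nm, ".json")))
                write.csv(all$summary, file.path(out_dir, "summary.csv"),
                          row.names = FALSE)
                message("summary written to ",
                        file.path(out_dir, "summary.csv"))
            },
            complexity = {
                .cliCheckFlags(flags, "out")
                ledger <- complexityReport()
                if (!is.null(flags$out))
                    jsonlite::write_json(ledger, flags$out,
                                         auto_unbox = TRUE, digits = NA,
                                         pretty = TRUE)
                else
                    print(ledger)
            },
            stop("unknown subcommand '", cmd, "'\n", .cliUsage()))
        0L
    }, error = function(e) {
        message("error: ", conditionMessage(e))
        1L
    })
    invisible(status)
}
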