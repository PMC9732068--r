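#' Experiment configuration
#'
#' Collects every tunable of the simulate / static-infer / dynamic-infer
#' pipeline with its default. Defaults reproduce the reference study
#' conditions: a 100-neuron network (80 excitatory), out-degree 10,
#' excitatory delays uniform on 1--20 ms, STDP (0.1, 0.12, 20 ms) with
#' memory factor 0.9 and 10-mV cut-off, recordings up to 180 min analyzed
#' at several lengths, delay sweep 1--50 ms, and 5 repetitions.
#'
#' @param masterSeed integer; per-repetition seeds are derived from it.
#' @param nRepetitions independent repetitions (network rewired each time).
#' @param durationsMin analysis lengths (prefixes of one recording per
#'   repetition); the maximum is the simulated duration.
#' @param measures subset of \code{c("xcov", "xcorr", "te", "hote")}.
#' @param percentiles presence-threshold grid.
#' @param reportPercentiles thresholds at which precision is tabulated.
#' @param windowsMin DFC window widths (minutes).
#' @param matchToMin DFC/DSC sample-count matching width (minutes).
#' @param scale multiply all durations and window widths by this factor
#'   for quick scaled-down runs.
#' @param ... overrides passed to \code{\link{buildNetwork}}.
#' @return a named list (class \code{"synfcConfig"}).
#' @export
experimentConfig <- function(masterSeed = 1L, nRepetitions = 5L,
                             durationsMin = c(5, 10, 30, 60, 120, 180),
                             measures = c("xcov", "xcorr", "te", "hote"),
                             percentiles = 1:99,
                             reportPercentiles = c(90, 95),
                             windowsMin = c(1, 2, 5, 10, 15, 30),
                             matchToMin = 30, scale = 1, ...) {
    cfg <- list(masterSeed = as.integer(masterSeed),
                nRepetitions = as.integer(nRepetitions),
                durationsMin = sort(durationsMin * scale),
                measures = measures,
                percentiles = percentiles,
                reportPercentiles = reportPercentiles,
                windowsMin = windowsMin * scale,
                matchToMin = matchToMin * scale,
                network = list(...))
    class(cfg) <- "synfcConfig"
    cfg
}

#' @export
print.synfcConfig <- function(x, ...) {
    cat("synfc experiment config: seed", x$masterSeed, ",",
        x$nRepetitions, "repetitions, durations",
        paste(x$durationsMin, collapse = "/"), "min, measures",
        paste(x$measures, collapse = "/"), "\n")
    invisible(x)
}

#' Run the full simulate / infer / evaluate pipeline
#'
#' For each repetition a network is wired and simulated once at the
#' longest configured duration; static inference is then evaluated on
#' prefixes of that recording at every configured length, and
#' dynamic-vs-synaptic connectivity is evaluated at the full length for
#' every window width, with and without delay consistency. Metrics are
#' aggregated as mean and SEM across repetitions and written, together
#' with the resolved configuration and seed list, to \code{outDir}.
#'
#' @param config list from \code{\link{experimentConfig}}.
#' @param outDir output directory (created if missing).
#' @param verbose print per-stage progress.
#' @return invisibly, a list of the aggregated metric data.frames
#'   (\code{static}, \code{dfc}) as written to disk.
#' @export
runExperiment <- function(config, outDir, verbose = TRUE) {
    stopifnot(inherits(config, "synfcConfig"))
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    yaml::write_yaml(unclass(config), file.path(outDir, "config.yaml"))
    maxDur <- max(config$durationsMin)
    seeds <- config$masterSeed + seq_len(config$nRepetitions) - 1L
    statRows <- list(); dfcRows <- list()

    for (r in seq_len(config$nRepetitions)) {
        if (verbose) message("repetition ", r, " (seed ", seeds[r], ")")
        net <- do.call(buildNetwork,
                       c(list(seed = seeds[r]), config$network))
        sim <- simulateNetwork(net, maxDur, seed = seeds[r] + 10000L)
        ras <- raster(sim)

        for (dur in config$durationsMin) {
            tR <- c(1L, as.integer(dur * 60000))
            for (ms in config$measures) {
                fc <- staticFC(ras, ms, tRangeMs = tR)
                pr <- prCurve(fc, net, config$percentiles)
                row <- data.frame(rep = r, seed = seeds[r],
                                  durationMin = dur, measure = ms,
                                  aupr = auprScore(pr))
                for (p in config$reportPercentiles)
                    row[[paste0("precision", p)]] <-
                        pr$precision[pr$percentile == p]
                if (fc@signed) {
                    lab <- classifySynapseSign(fc)
                    truthSign <- ifelse(isExcitatory(net)[edges(net)$pre],
                                        "excitatory", "inhibitory")
                    at <- cbind(edges(net)$pre, edges(net)$post)
                    row$signAccuracy <- mean(lab[at] == truthSign,
                                             na.rm = TRUE)
                } else row$signAccuracy <- NA_real_
                dm <- try(delayMetrics(fc, net, 90), silent = TRUE)
                if (!inherits(dm, "try-error")) {
                    row$delayCorrelation <- dm$correlation
                    row$delayMaeMs <- dm$maeMs
                } else {
                    row$delayCorrelation <- NA_real_
                    row$delayMaeMs <- NA_real_
                }
                statRows[[length(statRows) + 1L]] <- row
            }
        }

        fcSel <- staticFC(ras, "xcov")
        prsSel <- selectDFCPairs(fcSel, net, mode = "truth")
        dscFull <- weightTrajectory(sim)
        for (Tw in config$windowsMin) {
            if (maxDur / Tw < 3) next
            dscW <- dscWindowed(dscFull, Tw)
            for (cons in c(TRUE, FALSE)) {
                dfc <- dfcSliding(ras, prsSel, Tw, "xcov",
                                  delayConsistent = cons)
                cr <- dfcDscCorrelation(dfc, dscW,
                                        matchToMin = config$matchToMin)
                dfcRows[[length(dfcRows) + 1L]] <-
                    data.frame(rep = r, seed = seeds[r], windowMin = Tw,
                               measure = "xcov", delayConsistent = cons,
                               meanCorrelation = cr$meanCorrelation,
                               nPairs = nrow(cr$perPair),
                               nExcluded = cr$nExcluded)
            }
        }
    }

    statics <- do.call(rbind, statRows)
    dfcs <- do.call(rbind, dfcRows)
    write.table(statics, file.path(outDir, "static_metrics.tsv"),
                sep = "\t", row.names = FALSE, quote = FALSE)
    write.table(dfcs, file.path(outDir, "dfc_metrics.tsv"),
                sep = "\t", row.names = FALSE, quote = FALSE)

    aggStatic <- aggregateSem(statics, c("durationMin", "measure"),
                              setdiff(names(statics),
                                      c("rep", "seed", "durationMin",
                                        "measure")))
    aggDfc <- aggregateSem(dfcs, c("windowMin", "delayConsistent"),
                           c("meanCorrelation"))
    write.table(aggStatic, file.path(outDir, "static_summary.tsv"),
                sep = "\t", row.names = FALSE, quote = FALSE)
    write.table(aggDfc, file.path(outDir, "dfc_summary.tsv"),
                sep = "\t", row.names = FALSE, quote = FALSE)
    invisible(list(static = statics, dfc = dfcs,
                   staticSummary = aggStatic, dfcSummary = aggDfc))
}

# mean +/- SEM over repetitions for each metric column
aggregateSem <- function(df, by, cols) {
    sem <- function(x) { x <- x[is.finite(x)]
        if (length(x) < 2) NA_real_ else sd(x) / sqrt(length(x)) }
    mfun <- function(x) mean(x[is.finite(x)])
    means <- stats::aggregate(df[cols], df[by], mfun)
    sems <- stats::aggregate(df[cols], df[by], sem)
    names(means)[match(cols, names(means))] <- paste0(cols, "_mean")
    names(sems)[match(cols, names(sems))] <- paste0(cols, "_sem")
    merge(means, sems, by = by)
}

#' Import a spike raster from two-column text
#'
#' Reads whitespace- or tab-separated lines of \code{neuron_id time_ms}
#' (header optional), bins at 1 ms, and collapses duplicate spikes within
#' a bin to one with a warning.
#'
#' @param path input file.
#' @param nNeurons total neuron count (default: the largest id seen).
#' @param durationMs raster length (default: the last spike's bin).
#' @return a \code{\link{SpikeRaster}}.
#' @export
importRaster <- function(path, nNeurons = NULL, durationMs = NULL) {
    tab <- tryCatch(read.table(path, header = FALSE,
                               col.names = c("neuron", "time")),
                    error = function(e) stop("cannot parse ", path, ": ",
                                             conditionMessage(e)))
    if (is.character(tab$neuron)) {        # header line present
        hdr <- tab[1, ]
        tab <- tab[-1, , drop = FALSE]
        tab$neuron <- as.integer(tab$neuron)
        tab$time <- as.numeric(tab$time)
    }
    if (!nrow(tab)) stop("no spikes found; zero-duration raster")
    bad <- which(!is.finite(tab$neuron) | !is.finite(tab$time) |
                 tab$time < 0 | tab$neuron < 1)
    if (length(bad))
        stop("malformed row(s): ", paste(head(bad, 5), collapse = ", "))
    bin <- as.integer(floor(tab$time)) + 1L    # t = 0 falls in bin 1
    if (is.null(nNeurons)) nNeurons <- max(tab$neuron)
    if (is.null(durationMs)) durationMs <- max(bin)
    st <- vector("list", nNeurons)
    dup <- 0L
    for (i in seq_len(nNeurons)) {
        b <- sort(bin[tab$neuron == i])
        d <- duplicated(b)
        dup <- dup + sum(d)
        st[[i]] <- b[!d]
    }
    if (dup > 0)
        warning(dup, " duplicate spike(s) within a 1-ms bin collapsed")
    new("SpikeRaster", spikeTimes = st, nNeurons = as.integer(nNeurons),
        durationMs = as.integer(durationMs), seed = NA_integer_,
        metadata = list(source = path))
}

#' Export a spike raster as two-column text
#'
#' Writes \code{neuron_id time_ms} lines (bin start times, so bin 1 is
#' time 0) plus a JSON sidecar with dimensions, seed and metadata.
#'
#' @param raster a \code{\link{SpikeRaster}}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
exportRaster <- function(raster, path) {
    st <- spikeTimes(raster)
    tab <- data.frame(neuron = rep.int(seq_along(st), lengths(st)),
                      time = unlist(st, use.names = FALSE) - 1L)
    write.table(tab, path, sep = "\t", row.names = FALSE,
                col.names = FALSE, quote = FALSE)
    jsonlite::write_json(list(nNeurons = raster@nNeurons,
                              durationMs = raster@durationMs,
                              seed = raster@seed,
                              metadata = raster@metadata),
                         paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
    invisible(path)
}
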