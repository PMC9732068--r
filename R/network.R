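#' Build the ground-truth recurrent network
#'
#' Wires a sparse directed network in which each excitatory neuron projects
#' to \code{outDegree} randomly chosen postsynaptic neurons of either type,
#' and each inhibitory neuron to \code{outDegree} randomly chosen
#' \emph{excitatory} neurons (no inhibitory-to-inhibitory synapses, no self
#' connections, no duplicate edges). Excitatory synapses receive an integer
#' conduction delay drawn uniformly from \code{delayRangeMs} and start at
#' \code{initExcWeight}; inhibitory synapses have a fixed 1-ms delay and
#' constant weight \code{inhWeight}.
#'
#' With the defaults (100 neurons, 80 excitatory, out-degree 10) the network
#' has exactly 800 excitatory and 200 inhibitory synapses.
#'
#' @param seed integer seed; the same seed reproduces the same wiring.
#' @param nNeurons,nExcitatory,outDegree network geometry.
#' @param delayRangeMs inclusive integer range of excitatory delays (ms).
#' @param initExcWeight,inhWeight initial weights (mV).
#' @param aPlus,aMinus,tauMs STDP potentiation/depression amplitudes and
#'   time constant.
#' @param memoryFactor carry-over applied to the accumulated weight change
#'   after each 1-s update.
#' @param wMax upper cut-off of excitatory weights (mV).
#' @return a \code{\link{SpikingNetwork}}.
#' @examples
#' net <- buildNetwork(seed = 1)
#' table(isExcitatory(net)[edges(net)$pre])
#' @export
buildNetwork <- function(seed = NULL, nNeurons = 100L, nExcitatory = 80L,
                         outDegree = 10L, delayRangeMs = c(1L, 20L),
                         initExcWeight = 6, inhWeight = -5,
                         aPlus = 0.1, aMinus = 0.12, tauMs = 20,
                         memoryFactor = 0.9, wMax = 10) {
    nNeurons <- as.integer(nNeurons); nExcitatory <- as.integer(nExcitatory)
    outDegree <- as.integer(outDegree)
    if (nNeurons < 2L || nExcitatory < 1L || nExcitatory >= nNeurons)
        stop("need at least one excitatory and one inhibitory neuron")
    if (outDegree < 0L || outDegree > nNeurons - 1L)
        stop("outDegree must lie in [0, nNeurons - 1]")
    if (outDegree > nExcitatory - 1L)
        stop("inhibitory neurons need outDegree distinct excitatory targets")
    if (!is.null(seed)) set.seed(seed)

    isExc <- c(rep(TRUE, nExcitatory), rep(FALSE, nNeurons - nExcitatory))
    pre <- post <- integer(0)
    for (i in seq_len(nNeurons)) {
        cand <- if (isExc[i]) setdiff(seq_len(nNeurons), i)
                else setdiff(which(isExc), i)
        tgt <- if (outDegree) sample(cand, outDegree) else integer(0)
        pre <- c(pre, rep.int(i, length(tgt)))
        post <- c(post, tgt)
    }
    exc <- isExc[pre]
    delay <- ifelse(exc,
                    sample(seq.int(delayRangeMs[1], delayRangeMs[2]),
                           length(pre), replace = TRUE),
                    1L)
    weight <- ifelse(exc, initExcWeight, inhWeight)
    ord <- order(pre, post)
    net <- new("SpikingNetwork", nNeurons = nNeurons, isExcitatory = isExc,
               edges = data.frame(pre = pre, post = post,
                                  delay = as.integer(delay),
                                  weight = weight)[ord, , drop = FALSE],
               stdp = list(aPlus = aPlus, aMinus = aMinus, tauMs = tauMs,
                           memoryFactor = memoryFactor, wMax = wMax),
               seed = if (is.null(seed)) NA_integer_ else as.integer(seed))
    rownames(net@edges) <- NULL
    validObject(net)
    net
}

#' Read/write a network as a delimited edge list
#'
#' The on-disk format is a tab-separated table with columns \code{pre},
#' \code{post}, \code{sign} (+1/-1), \code{delay_ms} and \code{w0}, plus a
#' JSON sidecar (same path with extension \code{.json}) holding neuron
#' types, STDP parameters and the wiring seed.
#'
#' @param network a \code{SpikingNetwork}.
#' @param path file path for the edge-list table.
#' @return \code{writeNetwork} returns \code{path} invisibly;
#'   \code{readNetwork} returns a \code{SpikingNetwork}.
#' @export
writeNetwork <- function(network, path) {
    e <- edges(network)
    tab <- data.frame(pre = e$pre, post = e$post,
                      sign = ifelse(isExcitatory(network)[e$pre], 1L, -1L),
                      delay_ms = e$delay, w0 = e$weight)
    write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
    meta <- list(nNeurons = nNeurons(network),
                 isExcitatory = isExcitatory(network),
                 stdp = network@stdp, seed = network@seed)
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
    invisible(path)
}

#' @rdname writeNetwork
#' @export
readNetwork <- function(path) {
    tab <- read.table(path, header = TRUE, sep = "\t")
    meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
    net <- new("SpikingNetwork",
               nNeurons = as.integer(meta$nNeurons),
               isExcitatory = as.logical(meta$isExcitatory),
               edges = data.frame(pre = as.integer(tab$pre),
                                  post = as.integer(tab$post),
                                  delay = as.integer(tab$delay_ms),
                                  weight = as.numeric(tab$w0)),
               stdp = meta$stdp,
               seed = if (is.null(meta$seed) || is.na(meta$seed))
                   NA_integer_ else as.integer(meta$seed))
    validObject(net)
    net
}
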