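#' Construct an MEALayout
#'
#' @param electrode_id character vector of unique electrode identifiers.
#' @param x,y electrode coordinates in micrometres (origin at array centre).
#' @param cluster_id integer cluster membership per electrode.
#' @param sampling_rate acquisition sampling rate in Hz.
#' @return a validated [MEALayout-class].
#' @export
#' @examples
#' MEALayout(c("a", "b", "c", "d"), x = c(0, 1, 0, 1) * 100,
#'           y = c(0, 0, 1, 1) * 100, cluster_id = 1:4)
MEALayout <- function(electrode_id, x, y, cluster_id, sampling_rate = 10000) {
    new("MEALayout", electrodeId = as.character(electrode_id),
        x = as.numeric(x), y = as.numeric(y),
        clusterId = as.integer(cluster_id),
        samplingRate = as.numeric(sampling_rate))
}

#' Construct a SpikeTrainSet
#'
#' @param layout an [MEALayout-class].
#' @param spikes named list of numeric spike-time vectors in seconds; names
#'   are electrode ids. Electrodes missing from the list get empty trains.
#' @param duration recording duration in seconds.
#' @return a validated [SpikeTrainSet-class].
#' @export
SpikeTrainSet <- function(layout, spikes = list(), duration) {
    ids <- electrodeId(layout)
    unknown <- setdiff(names(spikes), ids)
    if (length(unknown))
        stop("layout mismatch: unknown electrode id(s): ",
             paste(unknown, collapse = ", "))
    full <- stats::setNames(vector("list", length(ids)), ids)
    for (id in ids)
        full[[id]] <- if (id %in% names(spikes)) as.numeric(spikes[[id]])
                      else numeric(0)
    new("SpikeTrainSet", layout = layout, spikes = full,
        duration = as.numeric(duration))
}

#' Default four-quadrant 60-electrode layout
#'
#' The layout of the four-quadrant MEAs used for clustered cultures: 60
#' electrodes, 15 per quadrant, each quadrant a 4 x 4 grid (200 um pitch)
#' minus its innermost corner, quadrant centres offset 1100 um from the array
#' centre. Coordinates are a documented convention; any inter-quadrant
#' electrode distance exceeds the largest intra-quadrant pitch, so the four
#' electrode groups are geometrically separable, matching the four physically
#' separated neuronal assemblies grown under a cross-shaped mask.
#'
#' @param sampling_rate sampling rate in Hz (default 10000).
#' @return an [MEALayout-class] with 60 electrodes and clusters `1:4`.
#' @export
#' @examples
#' lay <- defaultLayout4Q()
#' table(clusterId(lay))
defaultLayout4Q <- function(sampling_rate = 10000) {
    pitch <- 200
    offs <- 1100
    # quadrant centres: 1 = (-,+), 2 = (+,+), 3 = (-,-), 4 = (+,-)
    centres <- rbind(c(-offs, offs), c(offs, offs), c(-offs, -offs),
                     c(offs, -offs))
    grid <- expand.grid(i = 0:3, j = 0:3)
    grid$dx <- (grid$i - 1.5) * pitch
    grid$dy <- (grid$j - 1.5) * pitch
    ids <- character(0); xs <- numeric(0); ys <- numeric(0); cl <- integer(0)
    for (q in 1:4) {
        cx <- centres[q, 1]; cy <- centres[q, 2]
        # drop the grid position closest to the array centre -> 15 electrodes
        px <- cx + grid$dx; py <- cy + grid$dy
        keep <- order(px^2 + py^2, decreasing = TRUE)[1:15]
        keep <- sort(keep)
        ids <- c(ids, sprintf("q%d_%02d", q, seq_len(15)))
        xs <- c(xs, px[keep]); ys <- c(ys, py[keep])
        cl <- c(cl, rep(q, 15))
    }
    MEALayout(ids, xs, ys, cl, sampling_rate)
}

#' Read / write an electrode layout file
#'
#' Layout files are CSV with columns `electrode_id`, `x_um`, `y_um`,
#' `cluster_id` and an optional commented header line
#' `# sampling_rate_hz: <value>`.
#'
#' @param path file path.
#' @param sampling_rate sampling rate in Hz, used if the file carries none.
#' @return `readLayout` returns an [MEALayout-class]; `writeLayout` returns
#'   `path` invisibly.
#' @export
readLayout <- function(path, sampling_rate = 10000) {
    if (!file.exists(path)) stop("layout file not found: ", path)
    hdr <- readLines(path, n = 5L)
    m <- regmatches(hdr, regexec("^#\\s*sampling_rate_hz:\\s*([0-9.eE+-]+)", hdr))
    rates <- vapply(m, function(g) if (length(g)) as.numeric(g[2]) else NA_real_,
                    numeric(1))
    if (any(!is.na(rates))) sampling_rate <- rates[!is.na(rates)][1]
    df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
    need <- c("electrode_id", "x_um", "y_um", "cluster_id")
    if (!all(need %in% names(df)))
        stop("layout file must have columns: ", paste(need, collapse = ", "))
    MEALayout(df$electrode_id, df$x_um, df$y_um, df$cluster_id, sampling_rate)
}

#' @rdname readLayout
#' @param layout an [MEALayout-class] to write.
#' @export
writeLayout <- function(layout, path) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("# sampling_rate_hz: %.10g", samplingRate(layout)), con)
    utils::write.csv(positions(layout), con, row.names = FALSE, quote = FALSE)
    invisible(path)
}

#' Pairwise electrode distances in micrometres
#'
#' @param layout an [MEALayout-class].
#' @return symmetric matrix of Euclidean distances, dimnames = electrode ids.
#' @export
electrodeDistances <- function(layout) {
    d <- as.matrix(stats::dist(cbind(layout@x, layout@y)))
    dimnames(d) <- list(layout@electrodeId, layout@electrodeId)
    d
}
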