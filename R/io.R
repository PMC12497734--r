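#' Read spike trains ("peak trains") from disk
#'
#' Two on-disk formats are supported:
#' \describe{
#'   \item{`csv`}{long form with columns `electrode_id`, `spike_time_s`
#'     (seconds), preceded by commented metadata lines `# duration_s:` and
#'     `# sampling_rate_hz:`. Electrodes absent from the file get empty
#'     trains.}
#'   \item{`mat`}{a restricted MATLAB v5 dialect matching deposited peak
#'     trains: one cell array (n_electrodes x 1) of numeric vectors of sample
#'     ticks at the layout sampling rate. Cells map to layout electrodes in
#'     order; ticks are converted to seconds. Uncompressed and
#'     zlib-compressed (v7) variables are handled; anything structurally
#'     different fails with a clear error rather than guessing.}
#' }
#' Times are seconds internally regardless of the on-disk unit.
#'
#' @param path file path.
#' @param format `"csv"` or `"mat"`.
#' @param layout the [MEALayout-class] the file refers to.
#' @param duration recording duration in seconds; for CSV taken from the
#'   file's metadata header when present.
#' @return a validated [SpikeTrainSet-class].
#' @export
readSpikeTrains <- function(path, format = c("csv", "mat"), layout,
                            duration = NULL) {
    format <- match.arg(format)
    if (!file.exists(path)) stop("spike-train file not found: ", path)
    switch(format,
        csv = .readSpikeTrainsCsv(path, layout, duration),
        mat = .readSpikeTrainsMat(path, layout, duration))
}

#' Write spike trains to disk
#'
#' Inverse of [readSpikeTrains()]. CSV round-trips bit-exactly (times are
#' written with 17 significant digits); MAT stores sample ticks at the layout
#' sampling rate, so times are quantized to the sampling grid.
#'
#' @param sts a [SpikeTrainSet-class].
#' @param path destination path.
#' @param format `"csv"` or `"mat"`.
#' @return `path`, invisibly.
#' @export
writeSpikeTrains <- function(sts, path, format = c("csv", "mat")) {
    format <- match.arg(format)
    ok <- switch(format,
        csv = try(.writeSpikeTrainsCsv(sts, path), silent = TRUE),
        mat = try(.writeSpikeTrainsMat(sts, path), silent = TRUE))
    if (inherits(ok, "try-error"))
        stop("failed to write spike trains to '", path, "': ",
             attr(ok, "condition")$message)
    invisible(path)
}

.readSpikeTrainsCsv <- function(path, layout, duration) {
    hdr <- readLines(path, n = 10L)
    grab <- function(key) {
        m <- regmatches(hdr, regexec(paste0("^#\\s*", key,
                                            ":\\s*([0-9.eE+-]+)"), hdr))
        v <- vapply(m, function(g) if (length(g)) as.numeric(g[2]) else
                    NA_real_, numeric(1))
        if (any(!is.na(v))) v[!is.na(v)][1] else NA_real_
    }
    dur <- grab("duration_s")
    if (!is.na(dur)) duration <- dur
    if (is.null(duration) || is.na(duration))
        stop("duration not given and not present in the file header")
    df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
    if (!all(c("electrode_id", "spike_time_s") %in% names(df)))
        stop("spike-train CSV must have columns electrode_id, spike_time_s")
    ids <- electrodeId(layout)
    unknown <- setdiff(unique(df$electrode_id), ids)
    if (length(unknown))
        stop("layout mismatch: unknown electrode id(s): ",
             paste(unknown, collapse = ", "))
    spikes <- split(df$spike_time_s, factor(df$electrode_id, levels = ids))
    SpikeTrainSet(layout, spikes, duration)
}

.writeSpikeTrainsCsv <- function(sts, path) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c(sprintf("# duration_s: %.17g", sts@duration),
                 sprintf("# sampling_rate_hz: %.10g", samplingRate(sts)),
                 "electrode_id,spike_time_s"), con)
    for (id in electrodeId(sts)) {
        tr <- sts@spikes[[id]]
        if (length(tr))
            writeLines(sprintf("%s,%.17g", id, tr), con)
    }
    path
}

.readSpikeTrainsMat <- function(path, layout, duration) {
    vars <- .mat5Read(path)
    cells <- Filter(function(v) is.list(v), vars)
    n <- length(electrodeId(layout))
    pick <- Filter(function(v) length(v) == n, cells)
    if (!length(pick))
        stop("MAT dialect mismatch: expected one cell array with ", n,
             " numeric peak trains; found ",
             if (length(vars)) paste(names(vars), collapse = ", ")
             else "no variables")
    trains <- pick[[1]]
    rate <- samplingRate(layout)
    spikes <- lapply(trains, function(ticks) {
        if (!is.numeric(ticks))
            stop("MAT dialect mismatch: non-numeric peak train cell")
        as.numeric(ticks) / rate
    })
    names(spikes) <- electrodeId(layout)
    if (is.null(duration)) {
        mx <- suppressWarnings(max(unlist(spikes), 0))
        duration <- max(mx, 1 / rate)
    }
    SpikeTrainSet(layout, spikes, duration)
}

.writeSpikeTrainsMat <- function(sts, path) {
    rate <- samplingRate(sts)
    ticks <- lapply(sts@spikes, function(tr) round(tr * rate))
    .mat5Write(path, list(peak_train = ticks))
    path
}

# ---- minimal MAT v5 container (restricted dialect) --------------------------
# Supports numeric arrays (any standard storage type) and cell arrays of
# numeric arrays; uncompressed or zlib-compressed elements; both endiannesses.
# Anything else raises an error naming the unsupported construct.

.mat5Read <- function(path) {
    raw <- readBin(path, "raw", file.size(path))
    if (length(raw) < 128) stop("not a MAT v5 file (too short): ", path)
    endian <- rawToChar(raw[127:128])
    endian <- switch(endian, "IM" = "little", "MI" = "big",
                     stop("not a MAT v5 file (bad endian indicator): ", path))
    vars <- list(); nms <- character(0)
    pos <- 129L
    while (pos <= length(raw)) {
        el <- .mat5Element(raw, pos, endian)
        if (el$type == 15L) {             # miCOMPRESSED: inflate and recurse
            payload <- memDecompress(el$data, type = "gzip")
            sub <- .mat5Element(payload, 1L, endian)
            v <- .mat5Matrix(sub, endian)
        } else if (el$type == 14L) {      # miMATRIX
            v <- .mat5Matrix(el, endian)
        } else {
            stop("unsupported top-level MAT element type: ", el$type)
        }
        vars <- c(vars, list(v$value)); nms <- c(nms, v$name)
        pos <- el$next_pos
    }
    names(vars) <- nms
    vars
}

# parse one tagged element starting at pos (1-based); handles the small
# element format (type and size packed into one word)
.mat5Element <- function(raw, pos, endian) {
    word <- readBin(raw[pos:(pos + 3)], "integer", 1, 4, endian = endian)
    small_size <- bitwAnd(bitwShiftR(word, 16L), 0xFFFFL)
    if (small_size != 0L) {
        type <- bitwAnd(word, 0xFFFFL)
        nbytes <- small_size
        data <- raw[(pos + 4):(pos + 3 + nbytes)]
        return(list(type = type, data = data, next_pos = pos + 8L))
    }
    type <- word
    nbytes <- readBin(raw[(pos + 4):(pos + 7)], "integer", 1, 4,
                      endian = endian)
    data <- if (nbytes > 0) raw[(pos + 8):(pos + 7 + nbytes)] else raw(0)
    pad <- (8L - nbytes %% 8L) %% 8L
    list(type = type, data = data, next_pos = pos + 8L + nbytes + pad)
}

.mat5Numeric <- function(el, endian) {
    fmt <- switch(as.character(el$type),
        "1" = list("integer", 1, TRUE),   # miINT8
        "2" = list("integer", 1, FALSE),  # miUINT8
        "3" = list("integer", 2, TRUE),   # miINT16
        "4" = list("integer", 2, FALSE),  # miUINT16
        "5" = list("integer", 4, TRUE),   # miINT32
        "6" = list("integer", 4, TRUE),   # miUINT32 (values fit in practice)
        "7" = list("numeric", 4, TRUE),   # miSINGLE
        "9" = list("numeric", 8, TRUE),   # miDOUBLE
        stop("unsupported MAT numeric storage type: ", el$type))
    n <- length(el$data) %/% fmt[[2]]
    as.numeric(readBin(el$data, fmt[[1]], n, fmt[[2]], signed = fmt[[3]],
                       endian = endian))
}

.mat5Matrix <- function(el, endian) {
    if (el$type != 14L) stop("expected a miMATRIX element, got type ", el$type)
    raw <- el$data
    pos <- 1L
    flags <- .mat5Element(raw, pos, endian); pos <- flags$next_pos
    fw <- readBin(flags$data[1:4], "integer", 1, 4, endian = endian)
    class_id <- bitwAnd(fw, 0xFFL)
    dims_el <- .mat5Element(raw, pos, endian); pos <- dims_el$next_pos
    dims <- readBin(dims_el$data, "integer", length(dims_el$data) %/% 4, 4,
                    endian = endian)
    name_el <- .mat5Element(raw, pos, endian); pos <- name_el$next_pos
    name <- rawToChar(name_el$data)
    if (class_id == 1L) {                 # mxCELL_CLASS
        n <- prod(dims)
        cells <- vector("list", n)
        for (i in seq_len(n)) {
            sub <- .mat5Element(raw, pos, endian)
            v <- .mat5Matrix(sub, endian)
            cells[[i]] <- v$value
            pos <- sub$next_pos
        }
        return(list(name = name, value = cells))
    }
    if (class_id %in% c(6L, 7L, 8L:15L)) {  # numeric classes (double..uint64)
        if (bitwAnd(fw, 0x0800L) != 0L)
            stop("complex MAT arrays are not supported")
        data_el <- .mat5Element(raw, pos, endian)
        return(list(name = name, value = .mat5Numeric(data_el, endian)))
    }
    stop("unsupported MAT array class: ", class_id,
         " (only numeric and cell arrays are handled)")
}

.mat5Write <- function(path, vars) {
    con <- file(path, "wb")
    on.exit(close(con))
    desc <- sprintf("MATLAB 5.0 MAT-file, written by clustMEA")
    hdr <- charToRaw(desc)
    hdr <- c(hdr, rep(as.raw(32L), 116 - length(hdr)))
    writeBin(hdr, con)
    writeBin(rep(as.raw(0L), 8), con)                       # subsys offset
    writeBin(as.raw(c(0x00, 0x01)), con)                    # version 0x0100
    writeBin(charToRaw("IM"), con)                          # little-endian
    for (nm in names(vars))
        writeBin(.mat5MatrixRaw(nm, vars[[nm]]), con)
    path
}

.mat5Tag <- function(type, payload) {
    pad <- (8L - length(payload) %% 8L) %% 8L
    c(writeBin(c(as.integer(type), length(payload)), raw(), size = 4,
               endian = "little"),
      payload, rep(as.raw(0L), pad))
}

.mat5MatrixRaw <- function(name, value) {
    if (is.list(value)) {
        class_id <- 1L
        dims <- c(length(value), 1L)
        body_data <- do.call(c, c(list(raw(0)),
                                  lapply(value, function(v)
                                      .mat5MatrixRaw("", v))))
    } else {
        class_id <- 6L
        dims <- c(length(value), if (length(value)) 1L else 0L)
        body_data <- .mat5Tag(9L, writeBin(as.numeric(value), raw(), size = 8,
                                           endian = "little"))
    }
    flags <- writeBin(c(class_id, 0L), raw(), size = 4, endian = "little")
    body <- c(.mat5Tag(6L, flags),
              .mat5Tag(5L, writeBin(as.integer(dims), raw(), size = 4,
                                    endian = "little")),
              .mat5Tag(1L, charToRaw(name)),
              body_data)
    .mat5Tag(14L, body)
}
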