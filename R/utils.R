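# Internal helpers shared across modules.

# Write a file atomically: build it under a temporary name in the same
# directory, then rename, so failures never leave partial outputs behind.
.writeAtomic <- function(path, writer) {
    tmp <- tempfile(tmpdir = dirname(path), fileext = ".part")
    ok <- FALSE
    on.exit(if (!ok && file.exists(tmp)) unlink(tmp))
    writer(tmp)
    if (!file.rename(tmp, path))
        stop(sprintf("could not move output into place at '%s'", path))
    ok <- TRUE
    invisible(path)
}

# Cheap deterministic hash of a configuration list (order-insensitive in
# names), recorded in reports so runs can be matched to their settings.
.configHash <- function(x) {
    flat <- unlist(x[order(names(x))], use.names = TRUE)
    s <- paste(names(flat), as.character(flat), sep = "=", collapse = ";")
    bytes <- utf8ToInt(s)
    h <- 5381
    for (b in bytes) h <- (h * 33 + b) %% 2147483647
    sprintf("%08x", as.integer(h))
}

# Sample variance with n-1 denominator over the rows of a (possibly sparse)
# matrix; pairs with .rowMeans for vectorized per-gene statistics.
.rowVars <- function(m) {
    n <- ncol(m)
    mu <- Matrix::rowMeans(m)
    ex2 <- Matrix::rowMeans(m * m)
    pmax(0, (ex2 - mu^2) * n / (n - 1))
}
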