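## internal helpers: argument checks, seeded RNG scopes, text archives

stopf <- function(...) stop(sprintf(...), call. = FALSE)

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x != round(x) || x < min)
    stopf("`%s` must be a single integer >= %d", name, min)
  as.integer(x)
}

check_number <- function(x, name, min = -Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stopf("`%s` must be a single finite number", name)
  if (strict && x <= min) stopf("`%s` must be > %g", name, min)
  if (!strict && x < min) stopf("`%s` must be >= %g", name, min)
  as.numeric(x)
}

check_matrix <- function(x, name) {
  if (!is.matrix(x) || !is.numeric(x) || any(!is.finite(x)))
    stopf("`%s` must be a finite numeric matrix", name)
  x
}

## evaluate `expr` under a private RNG stream; the global .Random.seed is
## restored afterwards so library calls never perturb user randomness
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

## ---- plain-text archive with bit-exact numeric round-trip ------------------
## header lines "key: value", a "---" separator, then per array:
## "name <ndim> <dims...>" followed by one line of %.17g values (column-major).

write_archive <- function(path, type, meta, arrays) {
  lines <- c(sprintf("actionrec-archive: %s", type),
             vapply(names(meta), function(k) {
               sprintf("%s: %s", k, paste(format(meta[[k]], digits = 17), collapse = " "))
             }, ""),
             "---")
  for (nm in names(arrays)) {
    a <- arrays[[nm]]
    d <- if (is.null(dim(a))) length(a) else dim(a)
    lines <- c(lines,
               paste(c(nm, length(d), d), collapse = " "),
               paste(sprintf("%.17g", as.numeric(a)), collapse = " "))
  }
  writeLines(lines, path)
  invisible(path)
}

read_archive <- function(path, type = NULL) {
  lines <- readLines(path)
  sep <- match("---", lines)
  if (is.na(sep)) stopf("not an actionrec archive: %s", path)
  meta <- list()
  for (ln in lines[seq_len(sep - 1L)]) {
    kv <- regmatches(ln, regexpr(": ", ln), invert = TRUE)[[1]]
    meta[[kv[1]]] <- kv[2]
  }
  if (!is.null(type) && !identical(meta[["actionrec-archive"]], type))
    stopf("archive at %s is not of type '%s'", path, type)
  arrays <- list()
  i <- sep + 1L
  while (i < length(lines)) {
    hdr <- strsplit(lines[i], " ", fixed = TRUE)[[1]]
    nm <- hdr[1]
    nd <- as.integer(hdr[2])
    dims <- as.integer(hdr[2 + seq_len(nd)])
    vals <- as.numeric(strsplit(lines[i + 1L], " ", fixed = TRUE)[[1]])
    if (nd > 1L) dim(vals) <- dims
    arrays[[nm]] <- vals
    i <- i + 2L
  }
  list(meta = meta, arrays = arrays)
}

meta_num <- function(meta, key) as.numeric(strsplit(meta[[key]], " ")[[1]])
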