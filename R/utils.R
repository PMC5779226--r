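# Numerically stable log(1 + exp(x)).
.softplus <- function(x) ifelse(x > 30, x, log1p(exp(x)))

# Reporting floor on p-values, matching the "p < 10^-15" convention.
.P_FLOOR <- 1e-15

.floorP <- function(p) {
  p <- max(min(p, 1), 0)
  list(p = max(p, .P_FLOOR), floored = p < .P_FLOOR)
}

.formatP <- function(p, floored) {
  if (floored) "p < 1e-15" else sprintf("p = %.3g", p)
}

# Run `expr` under a given seed without disturbing the caller's RNG stream.
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

.stopifnotFinite <- function(x, what) {
  if (!is.numeric(x) || any(!is.finite(x)))
    stop(what, " must be numeric and finite", call. = FALSE)
}

# Library column names follow <protein|input>_<time>[_rep<k>].
.libraryName <- function(fraction, protein, time, replicate, nReplicates) {
  base <- paste0(ifelse(fraction == "input", "input", protein), "_", time)
  if (nReplicates > 1L) paste0(base, "_rep", replicate) else base
}

.parseLibraryName <- function(nm) {
  rep <- rep(1L, length(nm))
  hasRep <- grepl("_rep[0-9]+$", nm)
  rep[hasRep] <- as.integer(sub("^.*_rep([0-9]+)$", "\\1", nm[hasRep]))
  core <- sub("_rep[0-9]+$", "", nm)
  pos <- regexpr("_[^_]+$", core)
  if (any(pos < 0))
    stop("library names must look like <protein|input>_<timepoint>: ",
         paste(nm[pos < 0], collapse = ", "), call. = FALSE)
  who <- substr(core, 1L, pos - 1L)
  time <- substr(core, pos + 1L, nchar(core))
  data.frame(
    fraction = ifelse(who == "input", "input", "IP"),
    protein = ifelse(who == "input", NA_character_, who),
    time_point = time, replicate = rep,
    row.names = nm, stringsAsFactors = FALSE)
}

# Format numeric columns at 6 significant digits for TSV output.
.signifCols <- function(df, digits = 6) {
  isNum <- vapply(df, is.double, logical(1))
  df[isNum] <- lapply(df[isNum], signif, digits = digits)
  df
}

.writeTSV <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
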