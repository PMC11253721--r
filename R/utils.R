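## internal helpers

## evaluate expr with a local RNG state seeded by `seed`; the caller's RNG
## stream is untouched
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

## derive a child seed from a parent seed and a stage tag, staying < 2^31
childSeed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(seed) * 1009 + h) %% .Machine$integer.max)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

## format numerics for lossless text round-trips
fmtNum <- function(x) {
  out <- formatC(x, digits = 17, format = "g")
  out[is.na(x)] <- "NA"
  trimws(out)
}

## detect comma vs tab delimiter from the header line
detectDelim <- function(path) {
  hdr <- readLines(path, n = 1L)
  if (lengths(regmatches(hdr, gregexpr("\t", hdr))) >=
      lengths(regmatches(hdr, gregexpr(",", hdr)))) "\t" else ","
}

writeDelim <- function(df, path, sep = ",") {
  num <- vapply(df, is.numeric, logical(1))
  for (j in which(num)) df[[j]] <- fmtNum(df[[j]])
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

readDelim <- function(path) {
  sep <- detectDelim(path)
  utils::read.table(path, header = TRUE, sep = sep, quote = "",
                    stringsAsFactors = FALSE, na.strings = "NA",
                    check.names = FALSE, comment.char = "")
}
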