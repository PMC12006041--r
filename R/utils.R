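# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
.with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Global cell key: barcodes are only unique within a 10x run, so every join
# is keyed on (donor_id, barcode).
cell_key <- function(donor_id, barcode) paste(donor_id, barcode, sep = "|")

# Read a delimited table from a path (sniffing tab vs comma from the header
# line) or pass a data.frame through unchanged.
.read_table_auto <- function(source) {
  if (is.data.frame(source)) return(source)
  stopifnot(is.character(source), length(source) == 1L)
  if (!file.exists(source)) stop("input file not found: ", source)
  header <- readLines(source, n = 1L)
  if (length(header) == 0L) {
    return(data.frame())
  }
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  utils::read.delim(source, sep = sep, stringsAsFactors = FALSE,
                    check.names = FALSE)
}

# All floating point output is serialized with 6 significant digits.
.fmt_num <- function(x) {
  ifelse(is.na(x), "NA", formatC(x, digits = 6L, format = "g"))
}

.write_tsv <- function(df, path) {
  num <- vapply(df, is.double, logical(1L))
  df[num] <- lapply(df[num], .fmt_num)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.write_matrix_tsv <- function(m, path, label = "row") {
  vals <- matrix(.fmt_num(m), nrow = nrow(m), dimnames = dimnames(m))
  df <- data.frame(rownames(m), vals, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df) <- c(label, colnames(m))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.stop_format <- function(...) stop("format error: ", ..., call. = FALSE)
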