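# internal helpers shared across modules

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's state afterwards so generators stay pure functions of
# (config, seed).
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# deterministic small integer derived from a string (restart seeds per strain)
string_seed <- function(x, base = 0L) {
  v <- utf8ToInt(x)
  as.integer((base + sum(v * seq_along(v))) %% .Machine$integer.max)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Infer strain class from strain identifiers
#'
#' Strain identifiers beginning with `"ref"` are treated as parental
#' reference cultures, `"kd"` as knockdown (DAmP) strains, and anything else
#' as knockout strains. Real exports with different naming can bypass this
#' by supplying a `strain_class` column directly.
#'
#' @param strain character vector of strain identifiers.
#' @return character vector in `{"reference","knockdown","knockout"}`.
#' @export
infer_strain_class <- function(strain) {
  cls <- rep("knockout", length(strain))
  cls[startsWith(strain, "ref")] <- "reference"
  cls[startsWith(strain, "kd")] <- "knockdown"
  cls
}

#' Read / write tab-separated pipeline tables
#'
#' Thin wrappers around [data.table::fread()] / [data.table::fwrite()] fixing
#' the tab separator so every intermediate file round-trips losslessly.
#'
#' @param path file path.
#' @param x a data.frame/data.table.
#' @return `read_tsv_table` returns a data.table; `write_tsv_table` returns
#'   `path` invisibly.
#' @export
read_tsv_table <- function(path) {
  data.table::fread(path, sep = "\t", header = TRUE, data.table = TRUE)
}

#' @rdname read_tsv_table
#' @export
write_tsv_table <- function(x, path) {
  data.table::fwrite(x, path, sep = "\t", quote = FALSE)
  invisible(path)
}
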