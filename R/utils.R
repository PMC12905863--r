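# Internal helpers shared across modules.

# Derive a stage-specific RNG seed from the master seed so each generator
# stage has its own reproducible stream (kept below 2^31).
stage_seed <- function(seed, stage) {
  (as.integer(seed) + 7919L * as.integer(stage)) %% .Machine$integer.max
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == floor(x)
}

is_prob <- function(x) is.numeric(x) && all(is.finite(x)) && all(x >= 0 & x <= 1)

#' Area under the ROC curve for a binary outcome
#'
#' Thin wrapper around \code{pROC::roc} with a fixed case level and direction,
#' so the AUC is the probability a case outranks a control (no automatic
#' direction flipping).
#'
#' @param y binary outcome vector (0 = control, 1 = case).
#' @param pred numeric predictor (e.g. fitted probability or linear score).
#' @return AUC as a plain number.
#' @keywords internal
auc_binary <- function(y, pred) {
  r <- pROC::roc(response = y, predictor = pred, levels = c(0, 1),
                 direction = "<", quiet = TRUE)
  as.numeric(pROC::auc(r))
}

#' Nagelkerke pseudo-R-squared of a fitted binomial glm
#'
#' @param fit a \code{glm} object (binomial family) or a \code{logistic_fit}.
#' @return Nagelkerke's R-squared in [0, 1].
#' @export
nagelkerke_r2 <- function(fit) {
  if (inherits(fit, "logistic_fit")) fit <- fit$glm
  n <- stats::nobs(fit)
  r2_cs <- 1 - exp((fit$deviance - fit$null.deviance) / n)
  r2_cs / (1 - exp(-fit$null.deviance / n))
}

# 32-bit FNV-1a over a canonical JSON rendering of a config list.
# The FNV prime multiply (x 16777619 mod 2^32) is decomposed as
# 2^24 + 2^8 + 147 so every intermediate stays exactly representable
# in a double; bitwXor works on < 2^31 halves.
config_hash <- function(x) {
  s <- jsonlite::toJSON(sort_named(x), auto_unbox = TRUE, digits = NA,
                        null = "null", force = TRUE)
  bytes <- utf8ToInt(enc2utf8(as.character(s)))
  h <- 2166136261
  for (b in bytes) {
    lb <- h %% 256  # the byte xor only touches the low 8 bits
    h <- (h - lb) + bitwXor(as.integer(lb), as.integer(b %% 256))
    h <- ((h %% 256) * 16777216 + (h * 256) %% 4294967296 +
            (h * 147) %% 4294967296) %% 4294967296
  }
  paste0(sprintf("%04x", as.integer(h %/% 65536)),
         sprintf("%04x", as.integer(h %% 65536)))
}

# Recursively sort list names so the hash is order-invariant.
sort_named <- function(x) {
  if (is.list(x)) {
    if (!is.null(names(x)) && any(nzchar(names(x)))) x <- x[order(names(x))]
    lapply(x, sort_named)
  } else x
}

write_tsv_file <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

read_tsv_file <- function(path) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE, check.names = FALSE)
}
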