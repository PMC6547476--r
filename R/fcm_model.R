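#' Create an order-k finite-context model
#'
#' Reference implementation of the finite-context model (FCM) unit: an
#' order-`k` Markov model over a finite alphabet with additive (pseudo-count)
#' smoothing.  The compiled sequence codec uses the same definition
#' internally; this R-level object is the contract surface used for
#' inspection and testing.
#'
#' @param order Context length `k` (non-negative integer).
#' @param alphabet Character vector of single-character symbols.
#' @param alpha Positive smoothing pseudo-count; with counts `c` the model
#'   assigns `P(s | ctx) = (c(ctx, s) + alpha) / (total(ctx) + alpha * A)`
#'   for alphabet size `A`, which is strictly positive and sums to one.
#' @return An object of class `fcm_model`.
#' @examples
#' m <- fcm_new(2, alpha = 1)
#' m <- fcm_observe(m, "ACGACG")
#' fcm_probability(m, "CG", "A")  # (1 + 1) / (1 + 4) = 0.4
#' @export
fcm_new <- function(order, alphabet = c("A", "C", "G", "T"), alpha = 1) {
  stopifnot(order >= 0, length(alphabet) >= 1, alpha > 0)
  structure(
    list(order = as.integer(order), alphabet = alphabet, alpha = alpha,
         counts = new.env(parent = emptyenv())),
    class = "fcm_model"
  )
}

#' Update a finite-context model with observed text
#'
#' Slides an order-`k` window over `text` and increments the count of each
#' symbol in its length-`k` context.  The first `k` symbols seed the context
#' and are not themselves counted (they have no full-length context).
#'
#' @param model An `fcm_model`.
#' @param text A single string over the model's alphabet.
#' @return The updated model.
#' @export
fcm_observe <- function(model, text) {
  stopifnot(inherits(model, "fcm_model"), is.character(text), length(text) == 1L)
  k <- model$order
  chars <- strsplit(text, "", fixed = TRUE)[[1L]]
  if (length(chars) <= k) return(model)
  bad <- setdiff(unique(chars), model$alphabet)
  if (length(bad)) stop(sprintf("symbol '%s' outside alphabet", bad[1L]))
  A <- length(model$alphabet)
  for (i in (k + 1L):length(chars)) {
    ctx <- if (k == 0L) "" else paste(chars[(i - k):(i - 1L)], collapse = "")
    key <- paste0("c", ctx)  # environments cannot hold the empty name
    row <- get0(key, envir = model$counts, ifnotfound = NULL)
    if (is.null(row)) {
      row <- stats::setNames(integer(A), model$alphabet)
    }
    row[[chars[i]]] <- row[[chars[i]]] + 1L
    assign(key, row, envir = model$counts)
  }
  model
}

#' Smoothed conditional probability from a finite-context model
#'
#' @param model An `fcm_model`.
#' @param context A string of exactly `model$order` symbols.  A context never
#'   seen behaves as all-zero counts (uniform prior `1 / A`).
#' @param symbol A single symbol from the alphabet.
#' @return The smoothed probability `P(symbol | context)`, strictly in (0, 1).
#' @export
fcm_probability <- function(model, context, symbol) {
  stopifnot(inherits(model, "fcm_model"))
  if (nchar(context) != model$order) {
    stop(sprintf("context length %d != model order %d", nchar(context), model$order))
  }
  if (!symbol %in% model$alphabet) {
    stop(sprintf("symbol '%s' outside alphabet", symbol))
  }
  A <- length(model$alphabet)
  row <- get0(paste0("c", context), envir = model$counts,
              ifnotfound = stats::setNames(integer(A), model$alphabet))
  (row[[symbol]] + model$alpha) / (sum(row) + model$alpha * A)
}
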