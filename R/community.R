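#' Immunity-class / strain structure of a phage community
#'
#' A community consists of `Nc >= 1` superinfection-immunity classes, each
#' holding one or more phage strains. A strain is identified within its class
#' by its lysogeny fraction `f` in `[0, 1]`: the probability that an
#' infection lysogenizes rather than lyses the host. Strains with `f = 0` are
#' obligate lytic and carry no lysogen population.
#'
#' State vectors are flattened in a stable, documented order: classes in
#' declaration order, strains within a class sorted by ascending `f`. Phage
#' densities for all strains come first, then lysogen densities for the
#' temperate (`f > 0`) strains in the same order. [strain_table()] exposes
#' the resulting index map.
#'
#' @param classes A list with one element per immunity class; each element a
#'   numeric vector of lysogeny fractions, distinct within the class.
#' @param overrides Optional per-strain parameter heterogeneity: a data frame
#'   with columns `class`, `f`, and any of `alpha`, `gamma`, `delta`, `k`,
#'   `b` holding multiplicative factors applied to the shared parameters
#'   (1 = unchanged). Rows identify strains by class index and f value.
#'
#' @return An object of class `"community_config"` with elements `classes`
#'   (the sorted f-lists), `n_classes`, `n_strains`, `n_lysogens`,
#'   `strains` (the flattening table) and `overrides`.
#' @export
#' @examples
#' ## three immunity classes, one obligate lytic + three temperate strains each
#' cfg <- community_config(rep(list(c(0, 0.1, 0.5, 0.9)), 3))
#' cfg$n_strains
#' strain_table(cfg)
community_config <- function(classes, overrides = NULL) {
  if (!is.list(classes) || length(classes) < 1)
    stop("'classes' must be a non-empty list of f-vectors", call. = FALSE)
  classes <- lapply(classes, function(fs) {
    fs <- as.numeric(fs)
    if (length(fs) < 1) stop("every class needs >= 1 strain", call. = FALSE)
    if (any(!is.finite(fs)) || any(fs < 0) || any(fs > 1))
      stop("lysogeny fractions must lie in [0, 1]; got ",
           paste(fs[!is.finite(fs) | fs < 0 | fs > 1], collapse = ", "),
           call. = FALSE)
    if (anyDuplicated(fs))
      stop("lysogeny fractions within a class must be distinct", call. = FALSE)
    sort(fs)
  })
  nc <- length(classes)
  tab <- do.call(rbind, lapply(seq_len(nc), function(ci) {
    data.frame(class = ci, f = classes[[ci]])
  }))
  tab$phage_index <- seq_len(nrow(tab))
  tab$lysogen_index <- NA_integer_
  temperate <- tab$f > 0
  tab$lysogen_index[temperate] <- seq_len(sum(temperate))
  cfg <- structure(
    list(classes = classes, n_classes = nc, n_strains = nrow(tab),
         n_lysogens = sum(temperate), strains = tab, overrides = NULL),
    class = "community_config")
  if (!is.null(overrides)) cfg$overrides <- validate_overrides(overrides, cfg)
  cfg
}

validate_overrides <- function(overrides, cfg) {
  if (!is.data.frame(overrides) ||
      !all(c("class", "f") %in% names(overrides)))
    stop("'overrides' must be a data frame with columns class and f",
         call. = FALSE)
  known <- c("class", "f", "alpha", "gamma", "delta", "k", "b")
  bad <- setdiff(names(overrides), known)
  if (length(bad))
    stop("unknown override column(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  key <- paste(overrides$class, signif(overrides$f, 12))
  skey <- paste(cfg$strains$class, signif(cfg$strains$f, 12))
  if (!all(key %in% skey))
    stop("override rows refer to strains not in the community", call. = FALSE)
  fac <- as.matrix(overrides[setdiff(names(overrides), c("class", "f"))])
  if (length(fac) && (any(!is.finite(fac)) || any(fac <= 0)))
    stop("override factors must be finite and positive", call. = FALSE)
  overrides
}

#' Strain index map of a community
#'
#' @param config A [community_config()].
#' @return A data frame with one row per strain: `class`, `f`,
#'   `phage_index` (position in the phage block of the flattened state) and
#'   `lysogen_index` (position in the lysogen block; `NA` for obligate lytic
#'   strains).
#' @export
strain_table <- function(config) {
  stopifnot(inherits(config, "community_config"))
  config$strains
}

#' Densities of a phage community
#'
#' @param P Numeric vector of phage densities (1/volume), one per strain in
#'   flattening order.
#' @param L Numeric vector of lysogen densities, one per temperate strain in
#'   flattening order.
#' @param config The [community_config()] the densities belong to.
#' @return An object of class `"community_state"`: list with fields `P`, `L`.
#' @export
#' @examples
#' cfg <- community_config(list(c(0, 0.5), 0.9))
#' st <- community_state(P = c(1e8, 1e7, 1e6), L = c(1e7, 1e8), cfg)
community_state <- function(P, L, config) {
  stopifnot(inherits(config, "community_config"))
  P <- as.numeric(P); L <- as.numeric(L)
  if (length(P) != config$n_strains)
    stop(sprintf("'P' must have %d entries (one per strain), got %d",
                 config$n_strains, length(P)), call. = FALSE)
  if (length(L) != config$n_lysogens)
    stop(sprintf("'L' must have %d entries (one per temperate strain), got %d",
                 config$n_lysogens, length(L)), call. = FALSE)
  if (any(!is.finite(P)) || any(!is.finite(L)))
    stop("densities must be finite", call. = FALSE)
  if (any(P < 0) || any(L < 0))
    stop("densities must be nonnegative", call. = FALSE)
  structure(list(P = P, L = L), class = "community_state")
}

#' Per-class lysogen totals
#'
#' The total lysogen density of each immunity class,
#' `L_c = sum over temperate strains f of L_cf`. Classes containing only
#' obligate lytic strains contribute 0.
#'
#' @param state A [community_state()].
#' @param config The matching [community_config()].
#' @return Numeric vector of length `config$n_classes`.
#' @export
class_lysogen_totals <- function(state, config) {
  check_state_dims(state, config)
  tab <- config$strains
  out <- numeric(config$n_classes)
  temperate <- !is.na(tab$lysogen_index)
  if (any(temperate)) {
    sums <- tapply(state$L[tab$lysogen_index[temperate]],
                   tab$class[temperate], sum)
    out[as.integer(names(sums))] <- as.numeric(sums)
  }
  out
}

check_state_dims <- function(state, config) {
  if (!inherits(state, "community_state"))
    stop("'state' must be a community_state", call. = FALSE)
  if (!inherits(config, "community_config"))
    stop("'config' must be a community_config", call. = FALSE)
  if (length(state$P) != config$n_strains ||
      length(state$L) != config$n_lysogens)
    stop("state dimensions do not match the community configuration",
         call. = FALSE)
  invisible(TRUE)
}

#' @export
print.community_config <- function(x, ...) {
  cat(sprintf("Phage community: %d immunity class(es), %d strain(s), %d temperate\n",
              x$n_classes, x$n_strains, x$n_lysogens))
  for (ci in seq_along(x$classes))
    cat(sprintf("  class %d: f = {%s}\n", ci,
                paste(format(x$classes[[ci]]), collapse = ", ")))
  if (!is.null(x$overrides))
    cat(sprintf("  per-strain parameter overrides on %d strain(s)\n",
                nrow(x$overrides)))
  invisible(x)
}

# Per-strain parameter matrix (n_strains x 5), shared values multiplied by
# any override factors. Column order: alpha, gamma, delta, k, b.
param_matrix <- function(params, config) {
  stopifnot(is_model_parameters(params))
  base <- c(params$alpha, params$gamma, params$delta, params$k, params$b)
  m <- matrix(base, nrow = config$n_strains, ncol = 5, byrow = TRUE,
              dimnames = list(NULL, c("alpha", "gamma", "delta", "k", "b")))
  ov <- config$overrides
  if (!is.null(ov)) {
    skey <- paste(config$strains$class, signif(config$strains$f, 12))
    for (r in seq_len(nrow(ov))) {
      i <- match(paste(ov$class[r], signif(ov$f[r], 12)), skey)
      for (col in intersect(names(ov), colnames(m)))
        m[i, col] <- m[i, col] * ov[[col]][r]
    }
  }
  m
}
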