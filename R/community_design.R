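#' Default five-species community pool
#'
#' Genus labels of the five soil bacteria that make up the model
#' community: *Achromobacter*, *Ochrobactrum*, *Pseudomonas*,
#' *Stenotrophomonas* and *Variovorax*.
#'
#' @return Character vector of five species labels.
#' @export
#' @examples
#' default_pool()
default_pool <- function() {
  c("Achromobacter", "Ochrobactrum", "Pseudomonas",
    "Stenotrophomonas", "Variovorax")
}

validate_pool <- function(pool, min_size = 1L) {
  if (!is.character(pool) || length(pool) == 0) {
    stop("species pool must be a nonempty character vector", call. = FALSE)
  }
  if (anyNA(pool) || any(!nzchar(pool))) {
    stop("species labels must be nonempty strings", call. = FALSE)
  }
  if (anyDuplicated(pool)) {
    stop("duplicate species labels in pool: ",
         paste(unique(pool[duplicated(pool)]), collapse = ", "),
         call. = FALSE)
  }
  if (any(grepl(";", pool, fixed = TRUE))) {
    stop("species labels must not contain ';'", call. = FALSE)
  }
  if (length(pool) < min_size) {
    stop("species pool must contain at least ", min_size, " species",
         call. = FALSE)
  }
  pool
}

#' Canonical composition identifier
#'
#' A community composition is identified by its sorted, semicolon-joined
#' member labels, so identifiers are order-independent and byte-stable.
#'
#' @param members Character vector of species labels.
#' @return Single string, e.g. `"Achromobacter;Pseudomonas"`.
#' @seealso [split_composition()]
#' @export
composition_id <- function(members) {
  if (length(members) == 0) stop("composition must be nonempty", call. = FALSE)
  if (anyDuplicated(members)) {
    stop("composition contains duplicate species", call. = FALSE)
  }
  paste(sort(members), collapse = ";")
}

#' @rdname composition_id
#' @param id Composition identifier string.
#' @export
split_composition <- function(id) {
  strsplit(id, ";", fixed = TRUE)[[1]]
}

#' Enumerate all community compositions
#'
#' All nonempty subsets of the species pool, as used in all-subset
#' co-culture (persistence) assays from monoculture up to the full
#' community. Order is deterministic: by subset size, then
#' lexicographically by member labels.
#'
#' @param pool Character vector of unique species labels.
#' @return List of character vectors (each sorted), length `2^n - 1`.
#' @export
#' @examples
#' length(enumerate_compositions(default_pool())) # 31
enumerate_compositions <- function(pool) {
  pool <- sort(validate_pool(pool))
  out <- list()
  for (k in seq_along(pool)) {
    out <- c(out, combn(pool, k, simplify = FALSE))
  }
  out
}

#' Enumerate the invasion-from-rare design
#'
#' Every focal species crossed with every nonempty resident community
#' drawn from the remaining species: each species is invaded from rare
#' into every species-by-diversity combination. For an `n`-species pool
#' this yields `n * (2^(n-1) - 1)` treatments (75 for five species).
#'
#' @param pool Character vector of unique species labels (length >= 2).
#' @return Data frame with columns `focal`, `residents` (semicolon-joined
#'   composition id) and `diversity` (number of resident species).
#' @export
#' @examples
#' nrow(enumerate_invasion_design(default_pool())) # 75
enumerate_invasion_design <- function(pool) {
  pool <- validate_pool(pool, min_size = 2L)
  focal <- sort(pool)
  rows <- lapply(focal, function(f) {
    subs <- enumerate_compositions(setdiff(pool, f))
    data.frame(
      focal = f,
      residents = vapply(subs, composition_id, character(1)),
      diversity = lengths(subs),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Enumerate the indirect-interaction design
#'
#' For each focal species, every subset of the remaining species with at
#' least two members: the community combinations in which an indirect
#' (higher-order) interaction on the focal can be estimated. For five
#' species this gives 55 focal-by-partners combinations.
#'
#' A pool with fewer than three species supports no such combination and
#' yields an empty design rather than an error.
#'
#' @param pool Character vector of unique species labels.
#' @return Data frame with columns `focal`, `partners` (semicolon-joined)
#'   and `diversity` (number of partner species).
#' @export
#' @examples
#' nrow(enumerate_indirect_design(default_pool())) # 55
enumerate_indirect_design <- function(pool) {
  pool <- validate_pool(pool)
  empty <- data.frame(focal = character(0), partners = character(0),
                      diversity = integer(0), stringsAsFactors = FALSE)
  if (length(pool) < 3) return(empty)
  focal <- sort(pool)
  rows <- lapply(focal, function(f) {
    subs <- Filter(function(s) length(s) >= 2,
                   enumerate_compositions(setdiff(pool, f)))
    data.frame(
      focal = f,
      partners = vapply(subs, composition_id, character(1)),
      diversity = lengths(subs),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Enumerate all directed species pairs
#'
#' All ordered (focal, partner) pairs with focal != partner; the set of
#' directed pairwise interaction estimates (20 for five species).
#'
#' @param pool Character vector of unique species labels (length >= 2).
#' @return Data frame with columns `focal` and `partner`.
#' @export
enumerate_ordered_pairs <- function(pool) {
  pool <- sort(validate_pool(pool, min_size = 2L))
  grid <- expand.grid(partner = pool, focal = pool,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[grid$focal != grid$partner, c("focal", "partner")]
  grid <- grid[order(grid$focal, grid$partner), ]
  rownames(grid) <- NULL
  grid
}
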