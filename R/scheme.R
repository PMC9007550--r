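#' Define an attribute scheme for a choice experiment
#'
#' An attribute scheme lists the attributes of the alternatives, their level
#' labels, the preference domain each attribute belongs to, and whether the
#' attribute's levels are ordered (ordered two-level attributes may be sign
#' constrained during estimation). Domains group attributes that share a
#' common individual-level random effect.
#'
#' @param attributes named list; each element is a character vector of level
#'   labels (>= 2 levels per attribute).
#' @param domains named integer vector mapping each attribute name to a
#'   domain index in `1:3` (or more generally `1:D_max`).
#' @param ordered optional named logical vector; `TRUE` marks attributes
#'   whose levels are ordered from least to most preferred. Defaults to
#'   `FALSE` for all attributes.
#' @param compound optional named list recording, for compound attributes,
#'   the data frame of component levels returned by
#'   [build_compound_attribute()]; used only for feasibility audits.
#' @return An object of class `attribute_scheme`.
#' @examples
#' sch <- attribute_scheme(
#'   attributes = list(venue = c("home", "clinic"), cost = c("low", "high")),
#'   domains = c(venue = 1, cost = 2)
#' )
#' scheme_n_contrasts(sch)
#' @export
attribute_scheme <- function(attributes, domains, ordered = NULL, compound = NULL) {
  stopifnot(is.list(attributes), length(attributes) >= 1)
  nms <- names(attributes)
  if (is.null(nms) || anyDuplicated(nms) || any(nms == ""))
    stop("attributes must be a uniquely named list")
  n_lev <- vapply(attributes, length, integer(1))
  if (any(n_lev < 2)) stop("every attribute needs at least 2 levels")
  if (!all(nms %in% names(domains)))
    stop("every attribute must be assigned to a domain")
  domains <- as.integer(domains[nms])
  if (anyNA(domains) || any(domains < 1))
    stop("domain indices must be positive integers")
  if (is.null(ordered)) {
    ordered <- stats::setNames(rep(FALSE, length(nms)), nms)
  } else {
    full <- stats::setNames(rep(FALSE, length(nms)), nms)
    full[names(ordered)] <- ordered
    ordered <- full
  }
  structure(
    list(
      attributes = attributes,
      domains = stats::setNames(domains, nms),
      ordered = ordered,
      compound = compound
    ),
    class = "attribute_scheme"
  )
}

#' @export
print.attribute_scheme <- function(x, ...) {
  cat("Attribute scheme:", length(x$attributes), "attributes,",
      scheme_total_levels(x), "levels,",
      scheme_n_contrasts(x), "free contrasts\n")
  for (a in names(x$attributes)) {
    cat(sprintf("  %s (domain %d%s): %s\n", a, x$domains[[a]],
                if (x$ordered[[a]]) ", ordered" else "",
                paste(x$attributes[[a]], collapse = " | ")))
  }
  invisible(x)
}

#' Number of levels per attribute
#' @param scheme an `attribute_scheme`
#' @return named integer vector
#' @export
scheme_n_levels <- function(scheme) {
  vapply(scheme$attributes, length, integer(1))
}

#' Total number of attribute levels in the scheme
#' @param scheme an `attribute_scheme`
#' @return integer
#' @export
scheme_total_levels <- function(scheme) sum(scheme_n_levels(scheme))

#' Number of free effects-coded contrasts (sum of L_a - 1)
#' @param scheme an `attribute_scheme`
#' @return integer
#' @export
scheme_n_contrasts <- function(scheme) sum(scheme_n_levels(scheme) - 1L)

# Column indices of each attribute in the free-contrast parameterization.
contrast_cols <- function(scheme) {
  L <- scheme_n_levels(scheme)
  ends <- cumsum(L - 1L)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  stats::setNames(Map(seq.int, starts, ends), names(scheme$attributes))
}

# Free-contrast columns belonging to the attributes of domain d.
domain_cols <- function(scheme, d) {
  cc <- contrast_cols(scheme)
  unlist(cc[scheme$domains == d], use.names = FALSE)
}

# Long index of expanded levels: one row per (attribute, level).
expanded_index <- function(scheme) {
  L <- scheme_n_levels(scheme)
  data.frame(
    attribute = rep(names(scheme$attributes), L),
    level = unlist(lapply(L, seq_len), use.names = FALSE),
    label = unlist(scheme$attributes, use.names = FALSE),
    stringsAsFactors = FALSE
  )
}

#' Combine two attributes into a compound attribute under feasibility rules
#'
#' Some pairs of levels of two conceptually distinct attributes cannot occur
#' together (for example couples counseling with self-disclosure of a test
#' result). Merging the two attributes into one compound attribute whose
#' levels are the feasible pairs lets a standard design generator respect
#' the rules automatically.
#'
#' @param first character vector of levels of the first component (varies
#'   fastest in the enumeration).
#' @param second character vector of levels of the second component.
#' @param forbidden list of length-2 character vectors `c(first_level,
#'   second_level)` naming infeasible pairs; `NULL` allows all pairs.
#' @param sep separator used in the compound level labels.
#' @return data frame with columns `label`, `first`, `second`, one row per
#'   feasible pair.
#' @examples
#' build_compound_attribute(c("a", "b"), c("x", "y"),
#'                          forbidden = list(c("b", "y")))
#' @export
build_compound_attribute <- function(first, second, forbidden = NULL, sep = "; ") {
  grid <- expand.grid(first = first, second = second,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  keep <- rep(TRUE, nrow(grid))
  for (rule in forbidden) {
    stopifnot(length(rule) == 2)
    keep <- keep & !(grid$first == rule[[1]] & grid$second == rule[[2]])
  }
  out <- grid[keep, , drop = FALSE]
  if (nrow(out) == 0)
    stop("feasibility rules forbid every level combination; inconsistent configuration")
  out$label <- paste(out$first, out$second, sep = sep)
  rownames(out) <- NULL
  out[, c("label", "first", "second")]
}

#' The default HIV-testing attribute scheme
#'
#' Five attributes describing hypothetical HIV testing options: testing
#' venue (3 levels), testing availability (2 ordered levels), type of sample
#' (3 levels), additional services (3 levels), and a 5-level compound of
#' pre-test counseling with partner notification. The compound attribute
#' keeps only feasible counseling x notification pairs: one-on-one or group
#' counseling may be paired with self-disclosure or confidential provider
#' notification, and couples counseling implies automatic disclosure of the
#' result to the partner. Domains: 1 = privacy and confidentiality (venue,
#' counseling/notification), 2 = invasiveness and perceived accuracy
#' (sample), 3 = accessibility and value (availability, services).
#'
#' @return An `attribute_scheme` with 16 levels and 11 free contrasts.
#' @examples
#' sch <- default_scheme()
#' scheme_total_levels(sch)  # 16
#' @export
default_scheme <- function() {
  counseling <- c("one-on-one counseling", "group counseling", "couples counseling")
  notification <- c("self-disclosure", "provider notification", "automatic disclosure")
  forbidden <- list(
    c("couples counseling", "self-disclosure"),
    c("couples counseling", "provider notification"),
    c("one-on-one counseling", "automatic disclosure"),
    c("group counseling", "automatic disclosure")
  )
  comp <- build_compound_attribute(counseling, notification, forbidden)
  attribute_scheme(
    attributes = list(
      venue = c("home", "health facility", "VCT center"),
      availability = c("weekdays only", "every day"),
      sample = c("arm (venipuncture)", "finger (finger prick)", "mouth (oral swab)"),
      services = c("HIV test only", "health check", "STI examination"),
      counseling_notification = comp$label
    ),
    domains = c(venue = 1, availability = 3, sample = 2,
                services = 3, counseling_notification = 1),
    ordered = c(availability = TRUE),
    compound = list(counseling_notification = comp)
  )
}

#' Read / write an attribute scheme as YAML
#'
#' @param scheme an `attribute_scheme`
#' @param path file path
#' @return `read_scheme` returns an `attribute_scheme`; `write_scheme`
#'   returns `path` invisibly.
#' @export
write_scheme <- function(scheme, path) {
  obj <- list(
    attributes = scheme$attributes,
    domains = as.list(scheme$domains),
    ordered = as.list(scheme$ordered)
  )
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_scheme
#' @export
read_scheme <- function(path) {
  obj <- yaml::read_yaml(path)
  attribute_scheme(
    attributes = lapply(obj$attributes, as.character),
    domains = unlist(obj$domains),
    ordered = unlist(obj$ordered)
  )
}
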