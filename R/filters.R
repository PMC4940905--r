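# Filtering annotated change sets by vocabulary term with subsumption.

# SBML containers whose child order carries no meaning for the encoded
# system. listOfRules and listOfEvents are deliberately treated as ordered
# (conservative default; override via the unordered argument of
# is_order_only()).
SBML_UNORDERED_CONTAINERS <- c(
  "listOfParameters", "listOfSpecies", "listOfReactions",
  "listOfCompartments", "listOfUnitDefinitions", "listOfFunctionDefinitions"
)
CELLML_UNORDERED_CONTAINERS <- character()

unordered_containers <- function(dialect) {
  switch(normalize_dialect(dialect),
         sbml = SBML_UNORDERED_CONTAINERS,
         cellml = CELLML_UNORDERED_CONTAINERS,
         character())
}

#' Does an operation only change element order?
#'
#' `TRUE` iff the operation is a `Move` that keeps its parent container
#' (same parent address before and after) and that container's element
#' order carries no semantics in the dialect (e.g. the SBML
#' `listOfParameters`). Such changes are serialization churn from
#' re-writing tools and can be suppressed with a filter profile's
#' `drop_order_only`.
#'
#' @param op A `change_op`.
#' @param dialect `"sbml"`, `"cellml"` or `"generic"`.
#' @param unordered Overrides the dialect's unordered-container tag list.
#' @return Logical scalar.
#' @export
is_order_only <- function(op, dialect, unordered = NULL) {
  if (!identical(op$kind, "Move")) return(FALSE)
  if (is.na(op$address_a) || is.na(op$address_b)) return(FALSE)
  pa <- address_parent(op$address_a)
  pb <- address_parent(op$address_b)
  if (!identical(pa, pb)) return(FALSE)
  tags <- address_tags(pa)
  container <- tags[length(tags)]
  container %in% (unordered %||% unordered_containers(dialect))
}

#' Create a change filter profile
#'
#' A change is kept iff (the include set is empty, or at least one of its
#' terms is subsumed by an include term) and none of its terms is subsumed
#' by an exclude term; order-only changes are dropped when
#' `drop_order_only`. A change's term set spans all branches: its change
#' type, XML entity, affected targets, intentions and reasons.
#'
#' @param include,exclude Character vectors of term ids (any branch).
#' @param drop_order_only Drop order-only moves (see [is_order_only()]).
#' @param use_subsumption When `FALSE`, exact term match only.
#' @return A `filter_profile` object.
#' @seealso [builtin_profile()] for the named "modeller" and "curator"
#'   profiles.
#' @export
filter_profile <- function(include = character(), exclude = character(),
                           drop_order_only = FALSE, use_subsumption = TRUE) {
  include <- unique(as.character(include))
  exclude <- unique(as.character(exclude))
  if (length(intersect(include, exclude))) {
    stop("include and exclude sets overlap: ",
         paste(intersect(include, exclude), collapse = ", "), call. = FALSE)
  }
  structure(list(include = include, exclude = exclude,
                 drop_order_only = isTRUE(drop_order_only),
                 use_subsumption = isTRUE(use_subsumption)),
            class = "filter_profile")
}

#' Named audience profiles
#'
#' `"modeller"` keeps changes to the model setup and definition layers and
#' drops annotation-layer and order-only changes; `"curator"` keeps
#' everything except order-only changes. Relevance depends on the audience,
#' so both are only starting points for custom [filter_profile()]s.
#'
#' @param name `"modeller"` or `"curator"`.
#' @return A `filter_profile`.
#' @export
builtin_profile <- function(name) {
  switch(match.arg(name, c("modeller", "curator")),
         modeller = filter_profile(include = c("ModelSetup", "ModelDefinition"),
                                   exclude = "ModelAnnotation",
                                   drop_order_only = TRUE),
         curator = filter_profile(drop_order_only = TRUE))
}

#' @export
print.filter_profile <- function(x, ...) {
  fmt <- function(v) if (length(v)) paste(v, collapse = ",") else "(none)"
  cat(sprintf("<filter_profile> include=%s exclude=%s drop_order_only=%s subsumption=%s\n",
              fmt(x$include), fmt(x$exclude), x$drop_order_only, x$use_subsumption))
  invisible(x)
}

annotation_terms <- function(ann) {
  unique(c(ann$change_term, ann$applies_to, ann$affects,
           ann$has_intention, ann$has_reason))
}

#' Filter an annotated change set by vocabulary terms
#'
#' @param annotations A `change_annotations` object from [annotate_delta()].
#' @param profile A `filter_profile`.
#' @param vocabulary The vocabulary used for subsumption.
#' @return The kept subset, again a `change_annotations` object.
#' @examples
#' \dontrun{
#' filter_changes(anns, filter_profile(include = "ChangedSpecification"))
#' }
#' @export
filter_changes <- function(annotations, profile,
                           vocabulary = comodi_vocabulary()) {
  stopifnot(inherits(profile, "filter_profile"))
  for (tm in c(profile$include, profile$exclude)) {
    if (!(tm %in% vocabulary$terms$id)) {
      stop("unknown term '", tm, "' in filter profile", call. = FALSE)
    }
  }
  subsumed <- if (profile$use_subsumption) {
    function(term, by) any(vapply(by, function(b) is_a(vocabulary, term, b), logical(1)))
  } else {
    function(term, by) term %in% by
  }
  keep <- vapply(annotations, function(ann) {
    if (profile$drop_order_only && isTRUE(ann$order_only)) return(FALSE)
    terms <- annotation_terms(ann)
    if (length(profile$include) &&
        !any(vapply(terms, subsumed, logical(1), by = profile$include))) {
      return(FALSE)
    }
    !any(vapply(terms, subsumed, logical(1), by = profile$exclude))
  }, logical(1))
  structure(annotations[keep], class = c("change_annotations", "list"))
}

#' Collapse a version series to the versions with relevant changes
#'
#' Given the annotated deltas between successive versions of a model,
#' returns the indices of the versions whose delta still contains at least
#' one change after filtering; runs of versions whose filtered deltas are
#' empty are dropped, so e.g. releases that merely upgrade the format
#' specification disappear when `ModelEncoding` changes are excluded.
#'
#' @param version_series List of `change_annotations`, ordered by version
#'   succession (element i annotates the delta leading to version i).
#' @param profile A `filter_profile`.
#' @param vocabulary The vocabulary used for subsumption.
#' @return Integer vector of version indices.
#' @export
collapse_versions <- function(version_series, profile,
                              vocabulary = comodi_vocabulary()) {
  keep <- vapply(seq_along(version_series), function(i) {
    length(filter_changes(version_series[[i]], profile, vocabulary)) > 0L
  }, logical(1))
  which(keep)
}
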