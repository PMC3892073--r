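#' @include store.R
NULL

#' Role and user administration
#'
#' Role names are unique (store-level constraint); users carry a set of role
#' names. Authentication is external — the store only evaluates
#' authorization against the caller-supplied user name.
#'
#' @param store a [ChemStore-class].
#' @param role role name.
#' @param user user name.
#' @param roles character vector of role names held by the user.
#' @return the store, invisibly.
#' @export
addRole <- function(store, role) {
  storeInsert(store, "roles", list(role = role))
  invisible(store)
}

#' @rdname addRole
#' @export
addUser <- function(store, user, roles = character()) {
  known <- .tbl(store, "roles")$role
  miss <- setdiff(roles, known)
  if (length(miss)) {
    .crStop("chemreg_not_found_error",
            sprintf("unknown role(s): %s", paste(miss, collapse = ", ")))
  }
  tbl <- .tbl(store, "users")
  rolesTxt <- paste(roles, collapse = ",")
  i <- which(tbl$user == user)
  if (length(i)) {
    tbl$roles[i] <- rolesTxt
    .tblReplace(store, "users", tbl)
  } else {
    storeInsert(store, "users", list(user = user, roles = rolesTxt))
  }
  invisible(store)
}

#' Build a security context for a user
#'
#' When security is disabled in the store configuration every predicate is
#' permissive and every user can see everything. An unknown user has no
#' roles.
#'
#' @param store a [ChemStore-class].
#' @param user user name, or `NULL` (anonymous).
#' @return a [SecurityContext-class].
#' @export
securityContext <- function(store, user = NULL) {
  enabled <- isTRUE(store@.env$config$security$enabled)
  if (is.null(user) || is.na(user)) {
    return(new("SecurityContext", enabled = enabled, user = "anonymous",
               roles = character()))
  }
  tbl <- .tbl(store, "users")
  i <- which(tbl$user == user)
  roles <- if (length(i) && nzchar(tbl$roles[i])) {
    strsplit(tbl$roles[i], ",", fixed = TRUE)[[1]]
  } else character()
  new("SecurityContext", enabled = enabled, user = user, roles = roles)
}

#' Read-role filter predicate
#'
#' Returns a vectorised predicate over `read_role` values that is composed
#' into queries (never applied after paging): a row is readable iff its
#' read role is null (world-readable) or among the context's roles. A
#' disabled context yields a constant-true predicate.
#'
#' @param context a [SecurityContext-class].
#' @param kind entity kind (informational).
#' @return `function(read_role) logical`.
#' @export
readablePredicate <- function(context, kind = "compound") {
  if (!context@enabled) {
    return(function(read_role) rep(TRUE, length(read_role)))
  }
  roles <- context@roles
  function(read_role) is.na(read_role) | read_role %in% roles
}

#' Method-level write guard
#'
#' When security is enabled, a write is allowed only if the permission map
#' grants one of the user's roles access to the entity kind; an absent entry
#' denies by default. Denial raises a `chemreg_authorization_error` before
#' any store access. When security is disabled every write is allowed.
#'
#' @param context a [SecurityContext-class].
#' @param operation operation name (informational, e.g. `"save"`).
#' @param kind entity kind (`"compound"`, `"containable"`, `"container"`).
#' @param permissions named list `kind -> character vector of roles`.
#' @return `TRUE`, invisibly, when allowed.
#' @export
guardWrite <- function(context, operation, kind, permissions = list()) {
  if (!context@enabled) return(invisible(TRUE))
  allowed <- permissions[[kind]]
  if (is.null(allowed) || !length(intersect(context@roles, allowed))) {
    .crStop("chemreg_authorization_error",
            sprintf("user '%s' may not %s %s entities", context@user, operation, kind))
  }
  invisible(TRUE)
}
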