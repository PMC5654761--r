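#' Published EID database composition counts
#'
#' Event counts from the published emerging-infectious-disease event
#' database: the original 1940-2004 compilation (all EID events and the
#' wildlife-zoonosis subset) and the updated 1940-2008 wildlife-zoonosis
#' compilation with its post-1970 analysis subset (events before 1970 are
#' dropped because decadal covariates start in 1970).
#'
#' @return Data frame with columns `database`, `scope`, `n_events`.
#' @export
eid_database_counts <- function() {
  utils::read.csv(system.file("extdata", "eid_event_counts.csv",
                              package = "eidhotspots"),
                  stringsAsFactors = FALSE)
}

lookup_count <- function(counts, database, scope) {
  n <- counts$n_events[counts$database == database & counts$scope == scope]
  if (length(n) != 1L) stop(sprintf("no unique count for %s/%s",
                                    database, scope))
  n
}

#' Wildlife-zoonosis share of the original EID database
#'
#' Percentage of the 1940-2004 EID events attributed to wildlife-origin
#' zoonoses, recomputed from the database composition counts.
#'
#' @param counts count table (default [eid_database_counts()]).
#' @return Percentage.
#' @export
wildlife_zoonosis_share <- function(counts = eid_database_counts()) {
  100 * lookup_count(counts, "original_1940_2004", "wildlife_zoonoses") /
    lookup_count(counts, "original_1940_2004", "all_eids")
}

#' Post-1970 retention share of the updated database
#'
#' Percentage of the updated 1940-2008 wildlife-zoonosis events retained
#' after the pre-1970 covariate filter — the fraction of the record the
#' models actually see.
#'
#' @param counts count table (default [eid_database_counts()]).
#' @return Percentage.
#' @export
post1970_retention <- function(counts = eid_database_counts()) {
  100 * lookup_count(counts, "updated_1940_2008",
                     "wildlife_zoonoses_post1970") /
    lookup_count(counts, "updated_1940_2008", "wildlife_zoonoses")
}
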