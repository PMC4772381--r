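#' Bundled example networks
#'
#' Small networks shipped with the package: `"karate"` is Zachary's karate
#' club social network (34 members, 78 ties; public domain), the standard
#' worked example for community detection; `"toy_barbell"` is two 4-cliques
#' joined by a single edge (8 vertices, 13 edges); `"toy_two_triangles"` is
#' two disjoint triangles (6 vertices, 6 edges). The toys are constructed in
#' code.
#'
#' @param name one of `"karate"`, `"toy_barbell"`, `"toy_two_triangles"`.
#' @return An [elpa_network].
#' @examples
#' load_fixture("karate")
#' @export
load_fixture <- function(name) {
  known <- c("karate", "toy_barbell", "toy_two_triangles")
  if (!is.character(name) || length(name) != 1L || !(name %in% known))
    stop(sprintf("unknown fixture; available: %s", paste(known, collapse = ", ")))
  switch(name,
    karate = read_edge_list(system.file("extdata", "karate.edgelist",
                                        package = "elpa", mustWork = TRUE)),
    toy_barbell = {
      k4 <- function(v) t(utils::combn(v, 2L))
      elpa_network(rbind(k4(1:4), k4(5:8), c(4L, 5L)))
    },
    toy_two_triangles =
      elpa_network(cbind(c(1, 2, 1, 4, 5, 4), c(2, 3, 3, 5, 6, 6))))
}

#' Ground-truth cover for the karate fixture
#'
#' The observed two-faction split of the club (instructor's side and
#' officer's side), as documented in the original field study.
#'
#' @return A two-group disjoint cover (list of character vectors).
#' @export
karate_truth <- function() {
  read_cover(system.file("extdata", "karate_truth.communities",
                         package = "elpa", mustWork = TRUE))
}

#' Sources for non-vendored reference networks
#'
#' The dolphins and college-football networks are not shipped with the
#' package (keeping it download-free); this helper prints their canonical
#' source URLs. Place the extracted edge list under the path of your choice
#' and pass it to [elpa()] or [read_edge_list()].
#'
#' @return Named character vector of URLs, invisibly (also printed).
#' @export
fixture_urls <- function() {
  urls <- c(
    dolphins = "https://websites.umich.edu/~mejn/netdata/dolphins.zip",
    football = "https://websites.umich.edu/~mejn/netdata/football.zip")
  for (nm in names(urls)) cat(sprintf("%-9s %s\n", nm, urls[[nm]]))
  invisible(urls)
}
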