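# Gear inference from trip speed profiles: features, k-means smoothing,
# rule-based assignment, and kappa validation against a licence registry.

#' Default thresholds of the rule-based gear assignment
#'
#' @return Named list: `paired_dist_m` and `paired_window_min` define
#'   synchronous proximity for the pair-trawl test, `paired_min` and
#'   `loiter_min` the rule thresholds, and `loiter_speed` / `trawl_speed`
#'   the speed windows entering the loitering and pairing fractions.
#' @export
classifier_thresholds <- function() {
  list(paired_dist_m = 300, paired_window_min = 2.5, paired_min = 0.3,
       loiter_min = 0.3, loiter_speed = 0.5, trawl_speed = c(2, 5),
       near_zero_mode = 1.5, port_buffer_km = 1)
}

#' Speed-profile features of a trip
#'
#' The feature vector behind the gear classifier: a normalised
#' speed-over-ground histogram on \[0, 15\] knots in 0.5-knot bins (30
#' values; faster pings are counted in the top bin), the loitering fraction
#' (share of pings below 0.5 kn and more than a port buffer away from the
#' trip endpoints) and the paired fraction (share of pings at trawl speed
#' spent within 300 m of a synchronous ping of another vessel).
#'
#' @param trip A trip `data.frame` (from [segment_trips()]).
#' @param fleet_pings Optional full ping table of the fleet; required for a
#'   non-zero paired fraction.
#' @param thresholds See [classifier_thresholds()].
#' @return Named numeric vector of length 32 (`s0` ... `s14.5`, `loiter`,
#'   `paired`); the histogram part sums to 1.
#' @export
speed_profile_features <- function(trip, fleet_pings = NULL,
                                   thresholds = classifier_thresholds()) {
  n <- nrow(trip)
  if (is.null(n) || n == 0L) stop("empty trip", call. = FALSE)
  breaks <- seq(0, 15, by = 0.5)
  sog <- pmin(trip$sog_knots, 14.999)
  hist_counts <- tabulate(findInterval(sog, breaks), nbins = 30L)
  hist_frac <- hist_counts / n

  d_start <- dist_to_point_km(trip$lon, trip$lat, c(trip$lon[1], trip$lat[1]))
  d_end <- dist_to_point_km(trip$lon, trip$lat, c(trip$lon[n], trip$lat[n]))
  loiter <- mean(trip$sog_knots < thresholds$loiter_speed &
                   d_start > thresholds$port_buffer_km &
                   d_end > thresholds$port_buffer_km)

  paired <- 0
  if (!is.null(fleet_pings)) {
    vid <- attr(trip, "vessel_id") %||% trip$vessel_id[1]
    others <- fleet_pings[fleet_pings$vessel_id != vid, , drop = FALSE]
    if (nrow(others) > 0L) {
      cand <- which(trip$sog_knots >= thresholds$trawl_speed[1] &
                      trip$sog_knots <= thresholds$trawl_speed[2])
      if (length(cand)) {
        ot <- as.numeric(others$timestamp)
        ord <- order(ot)
        ot <- ot[ord]
        olon <- others$lon[ord]; olat <- others$lat[ord]
        win <- thresholds$paired_window_min * 60
        hit <- vapply(cand, function(i) {
          t_i <- as.numeric(trip$timestamp[i])
          lo <- findInterval(t_i - win, ot) + 1L
          hi <- findInterval(t_i + win, ot)
          if (hi < lo) return(FALSE)
          dd <- geosphere::distHaversine(
            cbind(olon[lo:hi], olat[lo:hi]),
            c(trip$lon[i], trip$lat[i]))
          any(dd < thresholds$paired_dist_m)
        }, logical(1))
        paired <- sum(hit) / n
      }
    }
  }
  c(stats::setNames(hist_frac, paste0("s", breaks[-31])),
    loiter = loiter, paired = paired)
}

#' Cluster trip feature vectors
#'
#' k-means clustering of the speed-profile features, used to smooth
#' per-trip labels before the rule-based assignment. The within-cluster
#' sum of squares is non-increasing over iterations by construction of the
#' algorithm, and the result is deterministic under the seed.
#'
#' @param features Numeric matrix, one row per trip (e.g. rows of
#'   [speed_profile_features()]).
#' @param k Number of clusters; default 5, mirroring the five gear classes.
#' @param seed Integer RNG seed.
#' @return Integer vector of cluster labels (1..k) with attributes
#'   `objective` (total within-cluster SS) and `centers`.
#' @export
cluster_trips <- function(features, k = 5L, seed = 1L) {
  features <- as.matrix(features)
  if (nrow(features) < k) {
    stop("need at least k = ", k, " feature vectors, got ", nrow(features),
         call. = FALSE)
  }
  fit <- with_seed(seed, stats::kmeans(features, centers = k, nstart = 10,
                                       iter.max = 100))
  out <- fit$cluster
  attr(out, "objective") <- fit$tot.withinss
  attr(out, "centers") <- fit$centers
  out
}

# Rule-based gear for one feature vector. Order matters: pairing beats the
# speed mode, the faster beam-trawl band is checked before the otter-trawl
# band (beam trawls tow faster, so an overlapping mode goes to TBB), and
# the purse-seine test requires both loitering and a near-zero mode.
rule_gear <- function(feature, bands = gear_speed_bands(),
                      thresholds = classifier_thresholds()) {
  hist <- feature[1:30]
  loiter <- feature[[31L]]
  paired <- feature[[32L]]
  mids <- seq(0.25, 14.75, by = 0.5)
  mode_speed <- mids[which.max(hist)]
  if (paired > thresholds$paired_min) return("PTM")
  if (mode_speed >= bands$TBB[1] && mode_speed <= bands$TBB[2]) return("TBB")
  if (mode_speed >= bands$OTB[1] && mode_speed <= bands$OTB[2]) return("OTB")
  if (loiter > thresholds$loiter_min &&
      mode_speed <= thresholds$near_zero_mode) return("PS")
  "OTHER"
}

#' Vessel-level gear from its trips
#'
#' Applies the rule-based assignment to each trip's feature vector (or
#' accepts precomputed per-trip labels, e.g. cluster-smoothed ones) and
#' returns the majority gear over the vessel's trips; ties resolve to
#' `OTHER`. The result does not depend on trip order.
#'
#' @param features Matrix of the vessel's trip features (one row per trip),
#'   or `NULL` when `trip_labels` is given.
#' @param bands Speed bands, see [gear_speed_bands()].
#' @param thresholds See [classifier_thresholds()].
#' @param trip_labels Optional character vector of per-trip gear labels
#'   overriding the rule evaluation.
#' @return A single gear label.
#' @export
assign_gear <- function(features = NULL, bands = gear_speed_bands(),
                        thresholds = classifier_thresholds(),
                        trip_labels = NULL) {
  if (is.null(trip_labels)) {
    if (is.null(features)) stop("no trips to assign", call. = FALSE)
    features <- rbind(features)
    if (nrow(features) == 0L) stop("no trips to assign", call. = FALSE)
    trip_labels <- apply(features, 1L, rule_gear, bands = bands,
                         thresholds = thresholds)
  }
  if (length(trip_labels) == 0L) stop("no trips to assign", call. = FALSE)
  tab <- sort(table(trip_labels), decreasing = TRUE)
  if (length(tab) > 1L && tab[1] == tab[2]) return("OTHER")
  names(tab)[1]
}

#' Classify the gear of every vessel in a ping table
#'
#' End-to-end gear inference: trips are segmented, speed-profile features
#' computed, per-trip rule labels smoothed by majority within k-means
#' clusters, and each vessel assigned the majority gear over its trips.
#'
#' @param pings Ping table for the whole fleet.
#' @param bands Speed bands ([gear_speed_bands()]).
#' @param k Cluster count for the smoothing step; skipped when there are
#'   fewer trips than clusters.
#' @param seed RNG seed for the clustering.
#' @param max_gap_hours Trip segmentation threshold.
#' @param thresholds See [classifier_thresholds()].
#' @return A `data.frame` with columns `vessel_id`, `predicted_gear`,
#'   `n_trips`; per-trip labels are attached as attribute `trips`.
#' @export
classify_fleet_gears <- function(pings, bands = gear_speed_bands(), k = 5L,
                                 seed = 1L, max_gap_hours = 4,
                                 thresholds = classifier_thresholds()) {
  trips <- segment_trips(pings, max_gap_hours)
  if (length(trips) == 0L) stop("no trips in ping table", call. = FALSE)
  feats <- t(vapply(trips, speed_profile_features, numeric(32L),
                    fleet_pings = pings, thresholds = thresholds))
  labels <- apply(feats, 1L, rule_gear, bands = bands,
                  thresholds = thresholds)
  if (nrow(feats) >= k) {
    cl <- cluster_trips(feats, k = k, seed = seed)
    for (g in unique(cl)) {
      idx <- which(cl == g)
      tab <- sort(table(labels[idx]), decreasing = TRUE)
      if (length(tab) == 1L || tab[1] > tab[2]) {
        labels[idx] <- names(tab)[1]
      }
    }
  }
  vids <- vapply(trips, function(tp) attr(tp, "vessel_id") %||%
                   tp$vessel_id[1], character(1))
  vessels <- unique(vids)
  out <- data.frame(
    vessel_id = vessels,
    predicted_gear = vapply(vessels, function(v) {
      assign_gear(trip_labels = labels[vids == v])
    }, character(1)),
    n_trips = vapply(vessels, function(v) sum(vids == v), integer(1)),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "trips") <- data.frame(vessel_id = vids, trip_label = labels,
                                   stringsAsFactors = FALSE)
  out
}

#' Cohen's kappa for multiclass agreement
#'
#' Chance-corrected agreement \eqn{\kappa = (p_o - p_e)/(1 - p_e)} between
#' two equally long label vectors over their joint category set. Returns 1
#' for perfect agreement (including the degenerate case where both sides
#' are the same constant, where chance agreement is 1), values near 0 under
#' independence, and is symmetric in its arguments.
#'
#' @param predicted,reference Equal-length, non-empty label vectors.
#' @return Kappa in \[-1, 1\].
#' @export
cohen_kappa <- function(predicted, reference) {
  if (length(predicted) != length(reference)) {
    stop("predicted and reference must have equal length", call. = FALSE)
  }
  n <- length(predicted)
  if (n == 0L) stop("empty label vectors", call. = FALSE)
  levels <- union(unique(predicted), unique(reference))
  tab <- table(factor(predicted, levels), factor(reference, levels)) / n
  po <- sum(diag(tab))
  pe <- sum(rowSums(tab) * colSums(tab))
  if (abs(1 - pe) < .Machine$double.eps^0.5) return(1)
  (po - pe) / (1 - pe)
}

#' Map FAO gear codes to the five analysis classes
#'
#' Licence registries record FAO gear codes; the analysis uses five
#' classes. Codes without a dedicated class map to `OTHER`.
#'
#' @param codes Character vector of FAO gear codes.
#' @return Character vector of gear labels.
#' @export
fao_to_class <- function(codes) {
  map <- c(OTB = "OTB", OTT = "OTB", TBB = "TBB", PTM = "PTM", PTB = "PTM",
           PS = "PS", PS1 = "PS", PS2 = "PS", LA = "PS")
  out <- unname(map[codes])
  out[is.na(out)] <- "OTHER"
  out
}

#' Read a licence registry CSV
#'
#' Expects columns `vessel_id` and `licensed_gear` (FAO code); the code is
#' mapped to the five analysis classes with [fao_to_class()].
#'
#' @param path CSV path.
#' @return `data.frame` with `vessel_id`, `licensed_gear`, `gear_class`.
#' @export
read_gear_registry <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("vessel_id", "licensed_gear"), names(df))
  if (length(miss)) {
    stop("registry CSV is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  df$gear_class <- fao_to_class(df$licensed_gear)
  df
}
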