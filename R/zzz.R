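#' @keywords internal
#' @importFrom data.table := .N .I .SD data.table as.data.table setkey
#' @importFrom stats median sd qt runif rnorm dist setNames
"_PACKAGE"

.datatable.aware <- TRUE

# silence R CMD check notes for data.table column names used in NSE
utils::globalVariables(c(
  "time_ns", "lipid_id", "species", "bead", "role", "x", "y", "z",
  "leaflet", "replica", "px", "py", "fi", "pid", "cx", "cy", "bcx", "bcy",
  "dx", "dy", "i.x", "i.y", "bead_ord", "r_idx", "theta_idx", "density",
  "enrichment", "r_mid", "theta_mid", "N"))
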