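# Representative factor values that land in each category under the default
# cut-point table; used to enumerate category profiles in scoring tests.
rep_factor_values <- list(
  bmi_percentile = list(ideal = 50, intermediate = 90, poor = 96),
  blood_pressure = list(ideal = c(110, 70), intermediate = c(125, 70),
                        poor = c(150, 95)),
  cholesterol = list(ideal = 150, intermediate = 185, poor = 210),
  glucose = list(ideal = 90, intermediate = 110, poor = 130),
  smoking = list(ideal = "never", intermediate = "former", poor = "current"),
  physical_activity = list(ideal = 450, intermediate = 200, poor = 0),
  diet = list(ideal = 5, intermediate = 3, poor = 1)
)

# Build a risk_profile from a vector of category indices (1 = ideal,
# 2 = intermediate, 3 = poor), ordered as rep_factor_values.
profile_from_categories <- function(idx) {
  cats <- c("ideal", "intermediate", "poor")
  vals <- Map(function(f, i) rep_factor_values[[f]][[cats[i]]],
              names(rep_factor_values), idx)
  do.call(risk_profile, vals)
}

# Small resource catalog around a fixed home point; one resource per category
# plus near-duplicates for tie-breaking.
fixture_catalog_df <- function() {
  data.frame(
    name = c("Riverside Park", "Midtown Gym", "Green Grocer", "Hope Pantry",
             "City Rec Center", "Saturday Market", "Valley CSA",
             "Teen Weight Clinic", "Elm Street Garden", "Ariverside Park"),
    category = c("park_playground", "fitness_sports_center", "grocery_store",
                 "food_pantry", "community_recreation_center",
                 "farmers_market", "csa", "weight_management_program",
                 "community_garden", "park_playground"),
    lat = c(38.64, 38.63, 38.66, 38.70, 38.61, 38.65, 38.75, 38.62, 38.68,
            38.64),
    lon = c(-90.26, -90.20, -90.30, -90.22, -90.24, -90.19, -90.40, -90.21,
            -90.27, -90.26),
    address = paste(1:10, "Main St"),
    hours = rep("9-5", 10),
    amenities = c("playground; trails", "pool", "", "", "gym; pool", "", "",
                  "", "plots", ""),
    stringsAsFactors = FALSE
  )
}

write_fixture_catalog_csv <- function(path = tempfile(fileext = ".csv")) {
  utils::write.csv(fixture_catalog_df(), path, row.names = FALSE)
  path
}

write_fixture_catalog_geojson <- function(path = tempfile(fileext = ".geojson")) {
  df <- fixture_catalog_df()
  features <- lapply(seq_len(nrow(df)), function(i) {
    amen <- trimws(strsplit(df$amenities[i], ";")[[1]])
    amen <- amen[nzchar(amen)]
    list(type = "Feature",
         geometry = list(type = "Point",
                         coordinates = c(df$lon[i], df$lat[i])),
         properties = list(name = df$name[i], category = df$category[i],
                           address = df$address[i], hours = df$hours[i],
                           amenities = amen))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA)
  path
}

# One internally consistent synthetic-style patient row.
fixture_patient_row <- function(id = "p1", age_months = 180, sex = "male",
                                height_cm = 165, weight_kg = 80,
                                mvpa = 120, lat = 38.63, lon = -90.20) {
  list(id = id, age_months = age_months, sex = sex, height_cm = height_cm,
       weight_kg = weight_kg, systolic = 112, diastolic = 70,
       cholesterol = 160, glucose = 90, smoking = "never",
       mvpa_min_per_week = mvpa, diet_fruit = TRUE, diet_vegetable = FALSE,
       diet_whole_grains = TRUE, diet_ssb = FALSE, diet_snacking = TRUE,
       pa_willingness = 4, diet_willingness = 3, lat = lat, lon = lon,
       preferred_channel = "email")
}
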