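{
  "start_year": 2009,
  "initial_population": [5950000, 340000, 300000, 620000],
  "demography": {
    "years": [2009, 2010, 2011, 2012, 2013, 2014, 2015, 2016, 2017, 2018, 2019, 2020, 2021, 2022, 2023, 2024, 2025, 2026, 2027, 2028, 2029, 2030, 2031, 2032],
    "birth_inflow": [120000, 121086.956521739, 122173.913043478, 123260.869565217, 124347.826086957, 125434.782608696, 126521.739130435, 127608.695652174, 128695.652173913, 129782.608695652, 130869.565217391, 131956.52173913, 133043.47826087, 134130.434782609, 135217.391304348, 136304.347826087, 137391.304347826, 138478.260869565, 139565.217391304, 140652.173913043, 141739.130434783, 142826.086956522, 143913.043478261, 145000],
    "death_rate": {
      "under60": [0.0025, 0.0025, 0.0025, 0.0025, 0.0025, 0.0025, 0.0025, 0.0025, 0.0025, 0.0025, 0.0025, 0.0025, 0.0025, 0.0025, 0.0025, 0.0025, 0.0025, 0.0025, 0.0025, 0.0025, 0.0025, 0.0025, 0.0025, 0.0025],
      "b60_64": [0.008, 0.008, 0.008, 0.008, 0.008, 0.008, 0.008, 0.008, 0.008, 0.008, 0.008, 0.008, 0.008, 0.008, 0.008, 0.008, 0.008, 0.008, 0.008, 0.008, 0.008, 0.008, 0.008, 0.008],
      "b65_69": [0.013, 0.013, 0.013, 0.013, 0.013, 0.013, 0.013, 0.013, 0.013, 0.013, 0.013, 0.013, 0.013, 0.013, 0.013, 0.013, 0.013, 0.013, 0.013, 0.013, 0.013, 0.013, 0.013, 0.013],
      "b70plus": [0.05, 0.0495652173913044, 0.0491304347826087, 0.048695652173913, 0.0482608695652174, 0.0478260869565217, 0.0473913043478261, 0.0469565217391304, 0.0465217391304348, 0.0460869565217391, 0.0456521739130435, 0.0452173913043478, 0.0447826086956522, 0.0443478260869565, 0.0439130434782609, 0.0434782608695652, 0.0430434782608696, 0.0426086956521739, 0.0421739130434783, 0.0417391304347826, 0.041304347826087, 0.0408695652173913, 0.0404347826086957, 0.04]
    },
    "aging_rate": {
      "under60": [0.015, 0.0154782608695652, 0.0159565217391304, 0.0164347826086957, 0.0169130434782609, 0.0173913043478261, 0.0178695652173913, 0.0183478260869565, 0.0188260869565217, 0.019304347826087, 0.0197826086956522, 0.0202608695652174, 0.0207391304347826, 0.0212173913043478, 0.021695652173913, 0.0221739130434783, 0.0226521739130435, 0.0231304347826087, 0.0236086956521739, 0.0240869565217391, 0.0245652173913043, 0.0250434782608696, 0.0255217391304348, 0.026],
      "b60_64": [0.2, 0.2, 0.2, 0.2, 0.2, 0.2, 0.2, 0.2, 0.2, 0.2, 0.2, 0.2, 0.2, 0.2, 0.2, 0.2, 0.2, 0.2, 0.2, 0.2, 0.2, 0.2, 0.2, 0.2],
      "b65_69": [0.2, 0.2, 0.2, 0.2, 0.2, 0.2, 0.2, 0.2, 0.2, 0.2, 0.2, 0.2, 0.2, 0.2, 0.2, 0.2, 0.2, 0.2, 0.2, 0.2, 0.2, 0.2, 0.2, 0.2],
      "b70plus": [0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0]
    },
    "visit_rate": {
      "under60": [2.36, 2.41616513691665, 2.45778918316078, 2.49525826917484, 2.53026085696977, 2.56353674522429, 2.59549832484122, 2.62640676809146, 2.65644136988463, 2.68573230271518, 2.71437805641293, 2.74245555218888, 2.77002639869164, 2.79714096210037, 2.82384112405584, 2.85016221421082, 2.87613440307467, 2.90178373022974, 2.92713287922489, 2.95220177216923, 2.97700803326013, 3.0015673552437, 3.02589379278752, 3.05],
      "b60_64": [4.6, 4.6, 4.6, 4.6, 4.6, 4.6, 4.6, 4.6, 4.6, 4.6, 4.6, 4.6, 4.6, 4.6, 4.6, 4.6, 4.6, 4.6, 4.6, 4.6, 4.6, 4.6, 4.6, 4.6],
      "b65_69": [4.6, 4.6, 4.6, 4.6, 4.6, 4.6, 4.6, 4.6, 4.6, 4.6, 4.6, 4.6, 4.6, 4.6, 4.6, 4.6, 4.6, 4.6, 4.6, 4.6, 4.6, 4.6, 4.6, 4.6],
      "b70plus": [14.66, 14.6874306313467, 14.7431541247239, 14.8190852120015, 14.9120761688355, 15.0202365796217, 15.142256182635, 15.2771527485647, 15.4241520502528, 15.5826220263664, 15.7520331031914, 15.9319326034791, 16.1219273706438, 16.3216714847482, 16.5308572901338, 16.749208662957, 16.9764758438022, 17.2124313942753, 17.4568669799818, 17.7095907735685, 17.9704253313698, 18.2392058375165, 18.515778637156, 18.8]
    },
    "public_share": {
      "under60": [0.35388288109431, 0.35388288109431, 0.35388288109431, 0.35388288109431, 0.35388288109431, 0.35388288109431, 0.35388288109431, 0.35388288109431, 0.35388288109431, 0.35388288109431, 0.35388288109431, 0.35388288109431, 0.35388288109431, 0.35388288109431, 0.35388288109431, 0.35388288109431, 0.35388288109431, 0.35388288109431, 0.35388288109431, 0.35388288109431, 0.35388288109431, 0.35388288109431, 0.35388288109431, 0.35388288109431],
      "b60_64": [0.46, 0.46, 0.46, 0.46, 0.46, 0.46, 0.46, 0.46, 0.46, 0.46, 0.46, 0.46, 0.46, 0.46, 0.46, 0.46, 0.46, 0.46, 0.46, 0.46, 0.46, 0.46, 0.46, 0.46],
      "b65_69": [0.5, 0.5, 0.5, 0.5, 0.5, 0.5, 0.5, 0.5, 0.5, 0.5, 0.5, 0.5, 0.5, 0.5, 0.5, 0.5, 0.5, 0.5, 0.5, 0.5, 0.5, 0.5, 0.5, 0.5],
      "b70plus": [0.603347888450043, 0.603347888450043, 0.603347888450043, 0.603347888450043, 0.603347888450043, 0.603347888450043, 0.603347888450043, 0.603347888450043, 0.603347888450043, 0.603347888450043, 0.603347888450043, 0.603347888450043, 0.603347888450043, 0.603347888450043, 0.603347888450043, 0.603347888450043, 0.603347888450043, 0.603347888450043, 0.603347888450043, 0.603347888450043, 0.603347888450043, 0.603347888450043, 0.603347888450043, 0.603347888450043]
    }
  },
  "mix": {
    "weight": [0.4, 0.15, 0.2, 0.05, 0.2],
    "base_price": [230, 280, 1400, 250, 1380],
    "inflation_rate": [0.035, 0.035, 0.035, 0.035, 0.035],
    "reference_year": 2009
  },
  "uptake": {
    "w_max": 0.85,
    "growth_rate": 0.45,
    "midpoint_year": 2010
  },
  "substitution": {
    "from_public": 0.32,
    "from_private": 0.43,
    "induced": 0.25
  },
  "chronic": {
    "prevalence": [0.15, 0.47, 0.575, 0.732],
    "curve": {
      "amount": [0, 2000, 4000],
      "visits": [0, 6.5, 8.775]
    },
    "price": 212
  },
  "chronic_substitution": {
    "from_public": 0.6,
    "from_private": 0.25,
    "induced": 0.15
  },
  "carry_release": 0.5,
  "observed_expenditure": {
    "year": [2009, 2010, 2011, 2012, 2013, 2014, 2015, 2016],
    "amount_hkd": [52000000, 70000000, 90000000, 220000000, 510000000, 1100000000, 1300000000, 1400000000]
  },
  "provenance": ["assumed", "anchored", "anchored", "assumed", "anchored", "assumed", "anchored", "synthetic"],
  "meta": {
    "name": "hk-anchored",
    "description": "Reconstructed Hong Kong inputs calibrated against the published baseline and scenario trajectories"
  }
}
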