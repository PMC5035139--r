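# Critical values of the Anderson-Darling statistic for a generalised
# Pareto distribution with scale and shape estimated by the method of
# moments. Monte Carlo calibrated (20000 replicates per shape value,
# samples of 100 exceedances); regenerated by tools/make_ad_table.R.
# Rows: shape xi; columns: cumulative probability of the statistic.
.ad_xi_grid <- c(-0.4, -0.3, -0.2, -0.1, 0.0, 0.1, 0.2, 0.3, 0.4, 0.5, 0.6, 0.7, 0.8, 0.9, 1.0)
.ad_F_grid <- c(0.001, 0.005, 0.01, 0.025, 0.05, 0.1, 0.2, 0.3, 0.4, 0.5, 0.6, 0.7, 0.8, 0.9, 0.95, 0.975, 0.99, 0.995, 0.999)
.ad_crit <- matrix(c(
  0.12956, 0.16059, 0.18141, 0.21615, 0.25245, 0.30843, 0.39839, 0.48983, 0.58983, 0.70766, 0.86283, 1.06650, 1.36875, 1.90179, 2.56720, 3.35212, 4.77483, 6.44664, 19.34256,
  0.11607, 0.14598, 0.16149, 0.18821, 0.21709, 0.26117, 0.32980, 0.39472, 0.45954, 0.53623, 0.62508, 0.74455, 0.91792, 1.23753, 1.59819, 1.93320, 2.44186, 2.83272, 4.18170,
  0.10977, 0.13121, 0.14793, 0.17158, 0.19890, 0.23506, 0.29031, 0.34266, 0.39423, 0.45057, 0.52077, 0.61030, 0.74010, 0.98165, 1.21547, 1.47735, 1.80957, 2.13543, 2.88146,
  0.10803, 0.12982, 0.14125, 0.16365, 0.18610, 0.22005, 0.26969, 0.31505, 0.36242, 0.41194, 0.47207, 0.54890, 0.65349, 0.84780, 1.04901, 1.27235, 1.55230, 1.79517, 2.50973,
  0.10506, 0.12205, 0.13588, 0.15800, 0.17961, 0.21018, 0.25747, 0.29787, 0.34069, 0.38802, 0.44269, 0.50893, 0.60712, 0.77983, 0.95482, 1.14577, 1.40861, 1.60986, 2.00685,
  0.10070, 0.12289, 0.13477, 0.15414, 0.17554, 0.20396, 0.24688, 0.28574, 0.32439, 0.36932, 0.42283, 0.48762, 0.58137, 0.74343, 0.90540, 1.08233, 1.28814, 1.49064, 1.92217,
  0.10073, 0.11873, 0.13219, 0.15128, 0.17073, 0.19802, 0.24097, 0.28000, 0.32002, 0.36183, 0.41483, 0.48121, 0.57137, 0.72725, 0.89348, 1.07594, 1.37140, 1.55543, 2.25753,
  0.10237, 0.12206, 0.13182, 0.14997, 0.16993, 0.19827, 0.24315, 0.28169, 0.32343, 0.36969, 0.42432, 0.49207, 0.59011, 0.76682, 0.98985, 1.32609, 1.73302, 2.47164, 4.41491,
  0.09996, 0.12007, 0.13213, 0.15119, 0.17133, 0.19890, 0.24454, 0.28575, 0.32956, 0.38012, 0.44046, 0.51689, 0.63417, 0.90656, 1.37117, 1.96276, 3.25021, 4.62729, 7.79686,
  0.10280, 0.12105, 0.13324, 0.15373, 0.17446, 0.20335, 0.25070, 0.29751, 0.35044, 0.41072, 0.47983, 0.57157, 0.74138, 1.30094, 2.45456, 3.97647, 6.14028, 6.84136, 12.41645,
  0.10052, 0.12310, 0.13670, 0.15765, 0.18074, 0.21243, 0.26513, 0.31523, 0.37097, 0.43636, 0.52315, 0.64433, 1.04386, 2.37418, 4.14131, 6.32519, 9.15937, 12.20359, 17.19699,
  0.10760, 0.12435, 0.13757, 0.16046, 0.18537, 0.22055, 0.27794, 0.33408, 0.39929, 0.47457, 0.57212, 0.77284, 1.32454, 3.95777, 6.39744, 9.25014, 14.91257, 16.63061, 25.46131,
  0.10998, 0.13215, 0.14521, 0.16821, 0.19441, 0.23179, 0.29517, 0.36018, 0.43067, 0.51754, 0.66185, 1.09560, 2.36932, 6.15971, 9.37005, 15.63163, 20.44240, 25.21432, 36.68190,
  0.11195, 0.13824, 0.15193, 0.17688, 0.20580, 0.24931, 0.32204, 0.39653, 0.47865, 0.59247, 0.80907, 1.33318, 3.97855, 8.93924, 15.65582, 20.26263, 29.90441, 35.59100, 48.83140,
  0.11398, 0.13965, 0.15629, 0.18669, 0.22003, 0.26775, 0.35385, 0.43645, 0.53313, 0.67623, 1.06589, 2.37331, 6.15650, 12.40792, 20.21048, 29.69730, 41.43263, 48.39546, 63.58013
), nrow = 15, byrow = TRUE)
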