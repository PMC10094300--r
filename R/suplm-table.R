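# Asymptotic quantiles of the supLM statistic, trimming fraction 0.1.
# Rows: probabilities in .supLM_probs; columns k = 1..6 model parameters.
# Tabulated by Monte Carlo: 2e5 (k = 2) or 6e4 (other k) simulated
# k-dimensional Brownian bridges on a 2000-point time grid.
.supLM_trim <- 0.1
.supLM_probs <- c(0.005, 0.01, 0.015, 0.02, 0.025, 0.03, 0.035, 0.04, 0.045, 0.05, 0.055, 0.06, 0.065, 0.07, 0.075, 0.08, 0.085, 0.09, 0.095, 0.1, 0.105, 0.11, 0.115, 0.12, 0.125, 0.13, 0.135, 0.14, 0.145, 0.15, 0.155, 0.16, 0.165, 0.17, 0.175, 0.18, 0.185, 0.19, 0.195, 0.2, 0.205, 0.21, 0.215, 0.22, 0.225, 0.23, 0.235, 0.24, 0.245, 0.25, 0.255, 0.26, 0.265, 0.27, 0.275, 0.28, 0.285, 0.29, 0.295, 0.3, 0.305, 0.31, 0.315, 0.32, 0.325, 0.33, 0.335, 0.34, 0.345, 0.35, 0.355, 0.36, 0.365, 0.37, 0.375, 0.38, 0.385, 0.39, 0.395, 0.4, 0.405, 0.41, 0.415, 0.42, 0.425, 0.43, 0.435, 0.44, 0.445, 0.45, 0.455, 0.46, 0.465, 0.47, 0.475, 0.48, 0.485, 0.49, 0.495, 0.5, 0.505, 0.51, 0.515, 0.52, 0.525, 0.53, 0.535, 0.54, 0.545, 0.55, 0.555, 0.56, 0.565, 0.57, 0.575, 0.58, 0.585, 0.59, 0.595, 0.6, 0.605, 0.61, 0.615, 0.62, 0.625, 0.63, 0.635, 0.64, 0.645, 0.65, 0.655, 0.66, 0.665, 0.67, 0.675, 0.68, 0.685, 0.69, 0.695, 0.7, 0.705, 0.71, 0.715, 0.72, 0.725, 0.73, 0.735, 0.74, 0.745, 0.75, 0.755, 0.76, 0.765, 0.77, 0.775, 0.78, 0.785, 0.79, 0.795, 0.8, 0.805, 0.81, 0.815, 0.82, 0.825, 0.83, 0.835, 0.84, 0.845, 0.85, 0.855, 0.86, 0.865, 0.87, 0.875, 0.88, 0.885, 0.89, 0.895, 0.9, 0.905, 0.91, 0.915, 0.92, 0.925, 0.93, 0.935, 0.94, 0.945, 0.95, 0.955, 0.96, 0.965, 0.97, 0.975, 0.98, 0.985, 0.986, 0.987, 0.988, 0.989, 0.99, 0.991, 0.992, 0.993, 0.994, 0.995, 0.996, 0.997, 0.998, 0.999, 0.9995)
.supLM_quantiles <- matrix(c(
  0.864949, 0.986707, 1.074899, 1.145629, 1.200074, 1.254159, 1.303983, 1.346501,
  1.386060, 1.427498, 1.465184, 1.501941, 1.535841, 1.568061, 1.600807, 1.632482,
  1.664198, 1.693863, 1.723135, 1.750426, 1.777672, 1.804305, 1.832146, 1.861278,
  1.887374, 1.914941, 1.938371, 1.964851, 1.990460, 2.017233, 2.042347, 2.065861,
  2.089637, 2.110086, 2.134699, 2.158419, 2.180722, 2.205052, 2.229101, 2.251333,
  2.273966, 2.295876, 2.318885, 2.340307, 2.360934, 2.385282, 2.407107, 2.429525,
  2.450876, 2.474095, 2.495649, 2.518013, 2.543200, 2.565445, 2.587327, 2.607369,
  2.630053, 2.653494, 2.676731, 2.702937, 2.728061, 2.751921, 2.774657, 2.797606,
  2.821010, 2.844611, 2.866788, 2.888563, 2.908871, 2.931521, 2.956119, 2.981817,
  3.005521, 3.030361, 3.051482, 3.075902, 3.099643, 3.123514, 3.146435, 3.170183,
  3.194254, 3.218608, 3.243888, 3.267680, 3.292703, 3.315964, 3.339686, 3.365789,
  3.389712, 3.411981, 3.436694, 3.462945, 3.489891, 3.514894, 3.542504, 3.567739,
  3.595081, 3.622892, 3.648983, 3.675400, 3.703754, 3.727610, 3.754367, 3.783299,
  3.813327, 3.841892, 3.870371, 3.899438, 3.925533, 3.953024, 3.978819, 4.009100,
  4.041114, 4.072954, 4.104785, 4.134055, 4.164847, 4.197006, 4.225951, 4.259987,
  4.291007, 4.325385, 4.359385, 4.392440, 4.424519, 4.456488, 4.488082, 4.519768,
  4.554171, 4.585678, 4.622444, 4.658310, 4.693620, 4.729592, 4.765141, 4.808816,
  4.845884, 4.887517, 4.924345, 4.966081, 5.006572, 5.047511, 5.085523, 5.132975,
  5.174107, 5.218483, 5.265066, 5.310532, 5.355428, 5.401481, 5.454577, 5.506660,
  5.554582, 5.607607, 5.657836, 5.707908, 5.758289, 5.815266, 5.871181, 5.926396,
  5.989655, 6.051765, 6.108569, 6.174177, 6.238657, 6.305430, 6.378957, 6.455410,
  6.526078, 6.603572, 6.679212, 6.761387, 6.843605, 6.927730, 7.028792, 7.114580,
  7.213138, 7.311100, 7.420399, 7.532510, 7.643672, 7.764830, 7.890020, 8.026369,
  8.169133, 8.332189, 8.502239, 8.675103, 8.889312, 9.103311, 9.352941, 9.614359,
  9.941795, 10.294481, 10.646722, 11.169635, 11.801827, 11.981201, 12.189764, 12.339217,
  12.506343, 12.734802, 12.971821, 13.284399, 13.614132, 14.001341, 14.448312, 14.906477,
  15.517846, 16.321822, 18.061781, 19.606644, 1.847712, 2.047125, 2.195146, 2.305941,
  2.405845, 2.490803, 2.564135, 2.633523, 2.699636, 2.765040, 2.824654, 2.879076,
  2.935407, 2.986762, 3.033665, 3.078245, 3.124862, 3.170225, 3.214764, 3.258176,
  3.302140, 3.343995, 3.383344, 3.421890, 3.461649, 3.499849, 3.538054, 3.574622,
  3.610298, 3.645056, 3.679710, 3.715748, 3.752394, 3.788916, 3.823705, 3.857824,
  3.891415, 3.923504, 3.957644, 3.992210, 4.023840, 4.056624, 4.090309, 4.120885,
  4.152969, 4.186540, 4.218250, 4.249012, 4.281670, 4.314810, 4.346987, 4.378224,
  4.410155, 4.441885, 4.471795, 4.501176, 4.532695, 4.563803, 4.595549, 4.626513,
  4.657820, 4.687874, 4.719345, 4.750590, 4.782339, 4.812833, 4.844684, 4.875834,
  4.906513, 4.936434, 4.968166, 4.997929, 5.028570, 5.059962, 5.089574, 5.121490,
  5.153158, 5.184745, 5.216394, 5.249515, 5.281172, 5.311829, 5.345558, 5.376604,
  5.409622, 5.441695, 5.473949, 5.504613, 5.536994, 5.569898, 5.601933, 5.632593,
  5.665325, 5.699065, 5.731760, 5.765107, 5.798234, 5.832652, 5.867626, 5.900376,
  5.934323, 5.967964, 6.003108, 6.036827, 6.070482, 6.105493, 6.140256, 6.174314,
  6.208769, 6.246189, 6.283459, 6.319539, 6.356173, 6.392952, 6.430193, 6.466150,
  6.505576, 6.542332, 6.578959, 6.619019, 6.660628, 6.701309, 6.742070, 6.781537,
  6.824369, 6.864780, 6.909356, 6.952398, 6.995821, 7.040436, 7.083418, 7.127134,
  7.171595, 7.216110, 7.259942, 7.305360, 7.353330, 7.397997, 7.445820, 7.493686,
  7.539556, 7.590454, 7.641059, 7.690398, 7.744574, 7.796801, 7.848313, 7.901208,
  7.958084, 8.018127, 8.072279, 8.132571, 8.191395, 8.252690, 8.313922, 8.375929,
  8.436926, 8.499489, 8.565595, 8.636032, 8.707100, 8.775243, 8.847940, 8.921179,
  8.996796, 9.071020, 9.146970, 9.228953, 9.315482, 9.405010, 9.492827, 9.585423,
  9.675845, 9.779886, 9.880666, 9.990026, 10.101688, 10.209117, 10.328450, 10.451462,
  10.580189, 10.723568, 10.869366, 11.012926, 11.167299, 11.332604, 11.509878, 11.699403,
  11.915658, 12.146836, 12.403167, 12.694929, 13.004920, 13.390139, 13.801909, 14.335569,
  14.965511, 15.104547, 15.288843, 15.469784, 15.687642, 15.928001, 16.176850, 16.462897,
  16.803455, 17.177251, 17.657479, 18.243904, 18.918897, 19.782194, 21.151818, 22.854887,
  2.815684, 3.091423, 3.247449, 3.409134, 3.557192, 3.678237, 3.770861, 3.860200,
  3.944772, 4.029157, 4.097655, 4.174330, 4.241250, 4.299163, 4.359197, 4.422629,
  4.487571, 4.541890, 4.606902, 4.653125, 4.703718, 4.755458, 4.800380, 4.846548,
  4.892849, 4.944450, 4.992464, 5.034493, 5.075195, 5.122148, 5.168619, 5.213995,
  5.258731, 5.300003, 5.339965, 5.382484, 5.420027, 5.460741, 5.493789, 5.533684,
  5.573093, 5.609962, 5.650037, 5.692329, 5.729934, 5.768132, 5.807979, 5.842634,
  5.881578, 5.917580, 5.949530, 5.988256, 6.025737, 6.062043, 6.098789, 6.138486,
  6.173271, 6.212600, 6.245956, 6.280430, 6.320845, 6.356429, 6.395728, 6.427519,
  6.463651, 6.502436, 6.536623, 6.572358, 6.604272, 6.643482, 6.678412, 6.713402,
  6.750778, 6.792043, 6.824948, 6.863838, 6.901381, 6.936233, 6.970593, 7.003350,
  7.039499, 7.079725, 7.117676, 7.152986, 7.190089, 7.221919, 7.258683, 7.296603,
  7.335973, 7.369383, 7.407023, 7.445213, 7.484214, 7.522383, 7.564277, 7.604633,
  7.644705, 7.683592, 7.722820, 7.758679, 7.801321, 7.835435, 7.879282, 7.921192,
  7.961870, 8.001299, 8.041949, 8.083251, 8.127803, 8.168953, 8.207885, 8.249729,
  8.293713, 8.335046, 8.379203, 8.422130, 8.463262, 8.505545, 8.546669, 8.588277,
  8.631787, 8.670618, 8.718313, 8.761705, 8.807906, 8.859796, 8.906462, 8.953245,
  8.999482, 9.049327, 9.095220, 9.143492, 9.195422, 9.244074, 9.295384, 9.347420,
  9.394834, 9.444390, 9.499631, 9.551921, 9.606161, 9.662619, 9.719526, 9.773816,
  9.825187, 9.883326, 9.947279, 10.003863, 10.066825, 10.128274, 10.191191, 10.249533,
  10.317027, 10.378475, 10.447284, 10.515428, 10.580644, 10.655212, 10.724508, 10.806236,
  10.882805, 10.955153, 11.030391, 11.112352, 11.189613, 11.267265, 11.351750, 11.435060,
  11.534365, 11.630865, 11.735528, 11.831572, 11.926235, 12.032872, 12.151576, 12.268332,
  12.383504, 12.513569, 12.633261, 12.781676, 12.909195, 13.066534, 13.209452, 13.380317,
  13.550918, 13.727475, 13.934452, 14.143371, 14.373694, 14.619253, 14.901635, 15.198645,
  15.540196, 15.953771, 16.450232, 17.030199, 17.736792, 17.916895, 18.068991, 18.300768,
  18.525276, 18.767400, 19.015568, 19.262949, 19.619989, 19.959137, 20.338237, 20.853935,
  21.505409, 22.507888, 24.182577, 25.813320, 3.811050, 4.178099, 4.400669, 4.578851,
  4.728178, 4.862443, 4.975140, 5.075064, 5.164597, 5.258488, 5.351654, 5.429629,
  5.504979, 5.579616, 5.656054, 5.733264, 5.806130, 5.877645, 5.946516, 6.006667,
  6.065593, 6.127173, 6.186761, 6.248826, 6.305892, 6.360414, 6.411591, 6.463197,
  6.511548, 6.560823, 6.612757, 6.661116, 6.714814, 6.761984, 6.805973, 6.853756,
  6.902333, 6.951314, 6.996593, 7.043067, 7.086435, 7.130636, 7.176328, 7.218328,
  7.259747, 7.302846, 7.345592, 7.388834, 7.432811, 7.474704, 7.518355, 7.563603,
  7.609278, 7.649075, 7.692001, 7.732004, 7.773751, 7.811790, 7.846545, 7.885832,
  7.923033, 7.966909, 8.005244, 8.043685, 8.084145, 8.126048, 8.165721, 8.204380,
  8.246027, 8.282254, 8.324309, 8.361504, 8.400930, 8.436395, 8.481911, 8.520987,
  8.564785, 8.608650, 8.648690, 8.685303, 8.724766, 8.767500, 8.807178, 8.848804,
  8.886076, 8.926543, 8.967536, 9.010201, 9.050403, 9.088202, 9.127850, 9.167190,
  9.205974, 9.243144, 9.285417, 9.325711, 9.365314, 9.403569, 9.450505, 9.495093,
  9.537651, 9.579480, 9.625854, 9.669506, 9.714431, 9.758157, 9.801281, 9.845703,
  9.888687, 9.933953, 9.981032, 10.025568, 10.071705, 10.120222, 10.168869, 10.213844,
  10.259186, 10.306104, 10.351538, 10.401742, 10.445210, 10.494011, 10.537841, 10.587830,
  10.637915, 10.689168, 10.743492, 10.801708, 10.853827, 10.906140, 10.963655, 11.018452,
  11.075563, 11.137663, 11.191411, 11.247088, 11.302094, 11.355725, 11.413184, 11.468940,
  11.524912, 11.580940, 11.644606, 11.709326, 11.767540, 11.827852, 11.882236, 11.946728,
  12.007309, 12.078161, 12.146155, 12.209657, 12.281529, 12.348147, 12.413593, 12.480366,
  12.552869, 12.620626, 12.704133, 12.777033, 12.860352, 12.938931, 13.021595, 13.097002,
  13.188939, 13.281170, 13.377147, 13.468813, 13.568129, 13.674954, 13.778769, 13.886659,
  14.001669, 14.110679, 14.217245, 14.339082, 14.456726, 14.582934, 14.723421, 14.877696,
  15.019645, 15.164563, 15.330608, 15.523154, 15.686291, 15.881858, 16.078940, 16.308238,
  16.534040, 16.787928, 17.077017, 17.404000, 17.737023, 18.129639, 18.617983, 19.205671,
  19.902490, 20.070662, 20.246467, 20.418382, 20.692486, 20.925057, 21.132563, 21.378935,
  21.718340, 22.077708, 22.462441, 22.974147, 23.648995, 24.600819, 26.283192, 27.911055,
  4.852303, 5.233442, 5.502015, 5.708766, 5.881313, 6.031928, 6.155594, 6.262240,
  6.374888, 6.485245, 6.591296, 6.679147, 6.762562, 6.842605, 6.930450, 7.006846,
  7.080207, 7.146225, 7.217822, 7.280668, 7.348196, 7.414624, 7.476459, 7.535615,
  7.596434, 7.656963, 7.721953, 7.782152, 7.839045, 7.898053, 7.954078, 8.011945,
  8.069004, 8.125059, 8.177722, 8.229156, 8.282341, 8.335588, 8.388842, 8.439246,
  8.488053, 8.535021, 8.580016, 8.625976, 8.674580, 8.723702, 8.774823, 8.826587,
  8.873534, 8.918032, 8.964897, 9.016320, 9.059724, 9.105987, 9.148476, 9.197535,
  9.241724, 9.289155, 9.335491, 9.378729, 9.422720, 9.461829, 9.510377, 9.550210,
  9.596066, 9.640995, 9.682243, 9.723976, 9.771849, 9.817153, 9.860473, 9.905557,
  9.947665, 9.993862, 10.033917, 10.072933, 10.118256, 10.158517, 10.200307, 10.243100,
  10.287146, 10.331423, 10.373818, 10.417873, 10.457120, 10.498725, 10.541635, 10.582740,
  10.630322, 10.676367, 10.723830, 10.764947, 10.808322, 10.854818, 10.898248, 10.941855,
  10.989820, 11.035529, 11.076108, 11.119343, 11.165916, 11.215104, 11.260458, 11.307482,
  11.353145, 11.399832, 11.446385, 11.494227, 11.542393, 11.594937, 11.638728, 11.687029,
  11.736080, 11.784367, 11.831577, 11.878269, 11.925186, 11.971490, 12.023095, 12.076183,
  12.125477, 12.177933, 12.227353, 12.278827, 12.329321, 12.386224, 12.443009, 12.492515,
  12.543887, 12.603236, 12.659765, 12.714548, 12.770953, 12.819551, 12.878508, 12.941855,
  13.002862, 13.056586, 13.118616, 13.179712, 13.247615, 13.316258, 13.376612, 13.443154,
  13.512326, 13.577342, 13.634749, 13.696181, 13.759517, 13.836838, 13.909649, 13.985125,
  14.057222, 14.132335, 14.204869, 14.279454, 14.363549, 14.439584, 14.520264, 14.603290,
  14.687615, 14.765228, 14.850818, 14.929990, 15.026370, 15.136695, 15.237730, 15.331136,
  15.442013, 15.548012, 15.661511, 15.771536, 15.878361, 16.001247, 16.121764, 16.247017,
  16.374502, 16.503738, 16.645921, 16.804144, 16.971424, 17.137922, 17.313994, 17.480192,
  17.677056, 17.892640, 18.093939, 18.320249, 18.542942, 18.788965, 19.066408, 19.400992,
  19.803059, 20.224034, 20.684796, 21.274679, 22.053366, 22.268541, 22.452234, 22.675230,
  22.887781, 23.160503, 23.475838, 23.757135, 24.201088, 24.656121, 25.046757, 25.525678,
  26.183779, 27.258523, 29.077242, 31.150843, 5.835275, 6.271879, 6.547916, 6.771588,
  6.966817, 7.128768, 7.283721, 7.430918, 7.562540, 7.683190, 7.792049, 7.902867,
  7.992184, 8.081701, 8.167049, 8.257537, 8.339381, 8.424225, 8.499155, 8.573038,
  8.646254, 8.724692, 8.794792, 8.866566, 8.935295, 8.999868, 9.068394, 9.128083,
  9.187589, 9.249221, 9.308538, 9.368417, 9.423775, 9.484047, 9.535190, 9.589774,
  9.647678, 9.702411, 9.756089, 9.810862, 9.863093, 9.914869, 9.966676, 10.017549,
  10.072414, 10.121102, 10.179222, 10.230231, 10.279513, 10.330241, 10.379990, 10.428183,
  10.475582, 10.524517, 10.570859, 10.618159, 10.671239, 10.716691, 10.765367, 10.811572,
  10.859104, 10.906536, 10.953481, 10.997260, 11.045031, 11.089911, 11.130180, 11.174636,
  11.225512, 11.269170, 11.317038, 11.361120, 11.400044, 11.447070, 11.491514, 11.539004,
  11.585915, 11.629006, 11.680075, 11.730696, 11.780625, 11.822435, 11.871492, 11.925470,
  11.973257, 12.017892, 12.064051, 12.110456, 12.160041, 12.207438, 12.255746, 12.308140,
  12.349092, 12.396050, 12.445397, 12.490913, 12.537568, 12.585870, 12.634375, 12.679362,
  12.726958, 12.777435, 12.825014, 12.873032, 12.917381, 12.962531, 13.007762, 13.059292,
  13.117470, 13.164595, 13.215570, 13.266184, 13.321433, 13.373844, 13.424451, 13.475464,
  13.532473, 13.584951, 13.643606, 13.697755, 13.749562, 13.801173, 13.853821, 13.909566,
  13.965238, 14.024747, 14.080328, 14.140025, 14.201447, 14.258141, 14.314868, 14.371822,
  14.429564, 14.493612, 14.550196, 14.616867, 14.674114, 14.735728, 14.798535, 14.855982,
  14.920574, 14.994723, 15.059353, 15.122781, 15.192134, 15.258963, 15.320438, 15.392743,
  15.467565, 15.532868, 15.604707, 15.675441, 15.750089, 15.833387, 15.915712, 15.996690,
  16.079339, 16.153325, 16.237262, 16.327537, 16.412314, 16.500791, 16.593500, 16.688548,
  16.794540, 16.890306, 16.990103, 17.094258, 17.193861, 17.295141, 17.397394, 17.511057,
  17.634896, 17.755852, 17.883086, 18.019817, 18.149645, 18.284560, 18.439200, 18.593490,
  18.753729, 18.919051, 19.103983, 19.290151, 19.502043, 19.723340, 19.928255, 20.149214,
  20.409168, 20.688546, 20.996948, 21.345793, 21.716472, 22.096593, 22.583953, 23.182913,
  24.012227, 24.199299, 24.407902, 24.622521, 24.869807, 25.204371, 25.489380, 25.817613,
  26.242113, 26.691728, 27.328392, 27.930625, 28.741559, 29.793399, 31.322214, 33.268421
), ncol = 6, dimnames = list(NULL, paste0('k', 1:6)))
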