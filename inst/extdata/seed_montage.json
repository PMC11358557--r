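{
  "channels": ["FP1", "FPZ", "FP2", "AF3", "AF4", "F7", "F5", "F3", "F1", "FZ", "F2", "F4", "F6", "F8", "FT7", "FC5", "FC3", "FC1", "FCZ", "FC2", "FC4", "FC6", "FT8", "T7", "C5", "C3", "C1", "CZ", "C2", "C4", "C6", "T8", "TP7", "CP5", "CP3", "CP1", "CPZ", "CP2", "CP4", "CP6", "TP8", "P7", "P5", "P3", "P1", "PZ", "P2", "P4", "P6", "P8", "PO7", "PO5", "PO3", "POZ", "PO4", "PO6", "PO8", "CB1", "O1", "OZ", "O2", "CB2"],
  "positions": {
    "FP1": [-0.1146, 0.9],
    "FPZ": [0, 0.9],
    "FP2": [0.1146, 0.9],
    "AF3": [-0.2479, 0.72],
    "AF4": [0.2479, 0.72],
    "F7": [-0.8535, 0.54],
    "F5": [-0.6401, 0.54],
    "F3": [-0.4267, 0.54],
    "F1": [-0.2134, 0.54],
    "FZ": [0, 0.54],
    "F2": [0.2134, 0.54],
    "F4": [0.4267, 0.54],
    "F6": [0.6401, 0.54],
    "F8": [0.8535, 0.54],
    "FT7": [-0.9704, 0.28],
    "FC5": [-0.7278, 0.28],
    "FC3": [-0.4852, 0.28],
    "FC1": [-0.2426, 0.28],
    "FCZ": [0, 0.28],
    "FC2": [0.2426, 0.28],
    "FC4": [0.4852, 0.28],
    "FC6": [0.7278, 0.28],
    "FT8": [0.9704, 0.28],
    "T7": [-1.01, 0],
    "C5": [-0.7575, 0],
    "C3": [-0.505, 0],
    "C1": [-0.2525, 0],
    "CZ": [0, 0],
    "C2": [0.2525, 0],
    "C4": [0.505, 0],
    "C6": [0.7575, 0],
    "T8": [1.01, 0],
    "TP7": [-0.9704, -0.28],
    "CP5": [-0.7278, -0.28],
    "CP3": [-0.4852, -0.28],
    "CP1": [-0.2426, -0.28],
    "CPZ": [0, -0.28],
    "CP2": [0.2426, -0.28],
    "CP4": [0.4852, -0.28],
    "CP6": [0.7278, -0.28],
    "TP8": [0.9704, -0.28],
    "P7": [-0.8535, -0.54],
    "P5": [-0.6401, -0.54],
    "P3": [-0.4267, -0.54],
    "P1": [-0.2134, -0.54],
    "PZ": [0, -0.54],
    "P2": [0.2134, -0.54],
    "P4": [0.4267, -0.54],
    "P6": [0.6401, -0.54],
    "P8": [0.8535, -0.54],
    "PO7": [-0.7082, -0.72],
    "PO5": [-0.4674, -0.72],
    "PO3": [-0.2337, -0.72],
    "POZ": [0, -0.72],
    "PO4": [0.2337, -0.72],
    "PO6": [0.4674, -0.72],
    "PO8": [0.7082, -0.72],
    "CB1": [-0.3299, -0.9],
    "O1": [-0.1375, -0.9],
    "OZ": [0, -0.9],
    "O2": [0.1375, -0.9],
    "CB2": [0.3299, -0.9]
  },
  "regions": {
    "left_hemisphere": ["FP1", "AF3", "F7", "F5", "F3", "F1", "FT7", "FC5", "FC3", "FC1", "T7", "C5", "C3", "C1", "TP7", "CP5", "CP3", "CP1", "P7", "P5", "P3", "P1", "PO7", "PO5", "PO3", "CB1", "O1"],
    "right_hemisphere": ["FP2", "AF4", "F2", "F4", "F6", "F8", "FC2", "FC4", "FC6", "FT8", "C2", "C4", "C6", "T8", "CP2", "CP4", "CP6", "TP8", "P2", "P4", "P6", "P8", "PO4", "PO6", "PO8", "O2", "CB2"],
    "anterior": ["FP1", "FPZ", "FP2", "AF3", "AF4", "F7", "F5", "F3", "F1", "FZ", "F2", "F4", "F6", "F8", "FT7", "FC5", "FC3", "FC1", "FCZ", "FC2", "FC4", "FC6", "FT8"],
    "posterior": ["TP7", "CP5", "CP3", "CP1", "CPZ", "CP2", "CP4", "CP6", "TP8", "P7", "P5", "P3", "P1", "PZ", "P2", "P4", "P6", "P8", "PO7", "PO5", "PO3", "POZ", "PO4", "PO6", "PO8", "CB1", "O1", "OZ", "O2", "CB2"],
    "left_anterior": ["FP1", "AF3", "F7", "F5", "F3", "F1", "FT7", "FC5", "FC3", "FC1"],
    "right_anterior": ["FP2", "AF4", "F2", "F4", "F6", "F8", "FC2", "FC4", "FC6", "FT8"],
    "left_posterior": ["TP7", "CP5", "CP3", "CP1", "P7", "P5", "P3", "P1", "PO7", "PO5", "PO3", "CB1", "O1"],
    "right_posterior": ["CP2", "CP4", "CP6", "TP8", "P2", "P4", "P6", "P8", "PO4", "PO6", "PO8", "O2", "CB2"]
  }
}
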