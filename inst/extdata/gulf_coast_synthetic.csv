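polygon,lon,lat
mainland,-100.0,32.0
mainland,-80.8,32.0
mainland,-80.2,28.5
mainland,-80.0,26.5
mainland,-80.3,25.2
mainland,-81.3,25.1
mainland,-81.8,26.5
mainland,-82.7,27.9
mainland,-83.7,29.9
mainland,-85.4,29.7
mainland,-86.3,30.4
mainland,-88.0,30.25
mainland,-89.1,30.2
mainland,-89.4,29.1
mainland,-91.3,29.6
mainland,-93.8,29.7
mainland,-95.3,28.9
mainland,-97.0,27.8
mainland,-97.5,25.9
mainland,-97.7,24.0
mainland,-96.5,22.8
mainland,-96.1,21.0
mainland,-95.9,19.0
mainland,-94.5,18.2
mainland,-92.9,18.4
mainland,-91.5,18.8
mainland,-90.7,19.8
mainland,-90.4,21.0
mainland,-88.9,21.6
mainland,-87.1,21.5
mainland,-86.8,20.5
mainland,-87.5,19.5
mainland,-87.7,18.3
mainland,-88.3,16.5
mainland,-88.9,15.6
mainland,-89.5,15.0
mainland,-100.0,15.0
mainland,-100.0,32.0
cuba,-84.9,21.9
cuba,-83.5,22.3
cuba,-81.5,23.2
cuba,-79.3,22.9
cuba,-77.2,21.6
cuba,-75.2,20.7
cuba,-75.1,19.9
cuba,-77.7,19.9
cuba,-80.5,21.9
cuba,-83.0,21.9
cuba,-84.5,21.2
cuba,-84.9,21.9
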