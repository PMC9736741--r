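group,a,b
"Spruce, fir",20.7385,-0.0102
Dahurian larch,67.413,-0.0141
Chinese pine,24.8265,-0.0234
Chinese red pine,7.21751,-0.0067
Other pine species,13.1198,-0.009
Cedarwood,3.75954,-0.0047
Cedar trees and other Chinese fir species,4.98967,-0.0025
Quercus,7.73245,-0.0048
Other hard broad class,6.9779,-0.0043
poplar,12.3106,-0.0069
eucalyptus,24.6966,-0.0137
yearning between lovers,9.53883,-0.0004
Other soft broad,8.12855,-0.0046
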