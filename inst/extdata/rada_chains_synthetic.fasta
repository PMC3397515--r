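>right_hand_rada_chain_synthetic stand-in for the S. solfataricus RadA chain of the right-handed filament crystal form
MSNELKQRALELGFISEEELQRVLTPKGIRELDRIFGGGYPKGSITEIFGEFGSGKTQL
AHQLAVNVQIPEEKGGLGGKAIYIDTEGTFRPERIKQIAEGMGLDPDEVLDNIIYARAY
TSDHQMELLDYVAAKFHEEGGIFKLLIIDSIMALFRVDFSGRGELAERQQKLAQMLSRL
>left_hand_rada_chain_synthetic stand-in for the S. solfataricus RadA chain of the left-handed filament crystal form
MSNELKQRALELGFISEEELQRVLTPKGIRELDRIFGGGYPKGSITEIFGEFGSGKTQL
AHQLAVNVQIPEEKGGLGGKAIYIDTEGTFRPERIKQIAEGMGLDPDEVLDNIIYARAY
TSDHQMELLDYVAAKFHEEGGIFKLLIIDSIMALFRVDFSGRGELAERQQKLAQMLSRL
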