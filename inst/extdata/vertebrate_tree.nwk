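(((((((human:6,chimp:6):10,orangutan:16):13,rhesus:29):61,(mouse:20,rat:20):70):7,((dog:80,horse:80):5,cow:85):12):213,chicken:310):140,zebrafish:450);
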