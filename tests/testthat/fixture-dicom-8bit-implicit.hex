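00000000000000000000000000000000000000000000000000000000000000000000000000000000000000000000000000000000000000000000000000000000000000000000000000000000000000000000000000000000000000000000000000000000000000000000000000000000000000000000000000000000000000004449434d02000000554c0400cc000000020001004f4200000200000000010200020055491a00312e322e3834302e31303030382e352e312e342e312e312e37000200030055494000312e322e3832362e302e312e333638303034332e382e3439382e36303730373733373335333338303739363136303934333731373433363834353435363830310200100055491200312e322e3834302e31303030382e312e32000200120055491c00312e322e3832362e302e312e333638303034332e382e3439382e31000200130053480e0050594449434f4d20332e302e3220080016001a000000312e322e3834302e31303030382e352e312e342e312e312e37000800180040000000312e322e3832362e302e312e333638303034332e382e3439382e363037303737333733353333383037393631363039343337313734333638343534353638303108006000020000004d4728000200020000000100280004000c0000004d4f4e4f4348524f4d453220280010000200000002002800110002000000030028000001020000000800280001010200000008002800020102000000070028000301020000000000e07f1000060000000005fa1180ff
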