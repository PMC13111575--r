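00000000000000000000000000000000000000000000000000000000000000000000000000000000000000000000000000000000000000000000000000000000000000000000000000000000000000000000000000000000000000000000000000000000000000000000000000000000000000000000000000000000000000004449434d02000000554c0400ce000000020001004f4200000200000000010200020055491a00312e322e3834302e31303030382e352e312e342e312e312e37000200030055494000312e322e3832362e302e312e333638303034332e382e3439382e33393635383039383031323734333930383631353135383331333235373736343536303935330200100055491400312e322e3834302e31303030382e312e322e31000200120055491c00312e322e3832362e302e312e333638303034332e382e3439382e31000200130053480e0050594449434f4d20332e302e32200800160055491a00312e322e3834302e31303030382e352e312e342e312e312e37000800180055494000312e322e3832362e302e312e333638303034332e382e3439382e333936353830393830313237343339303836313531353833313332353737363435363039353308006000435302004d47280002005553020001002800040043530c004d4f4e4f4348524f4d4532202800100055530200030028001100555302000400280000015553020010002800010155530200100028000201555302000f002800030155530200000028005210445304003130302028005310445302003220e07f10004f5700001800000000000100020003000a0014001e0028006400c8003075409c
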