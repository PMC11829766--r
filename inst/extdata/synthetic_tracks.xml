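<?xml version="1.0" encoding="UTF-8"?>
<TrackModel>
  <AllSpots>
    <Spot ID="1" FRAME="-2" POSITION_X="0" POSITION_Y="0" POSITION_Z="0"/>
    <Spot ID="2" FRAME="-1" POSITION_X="0" POSITION_Y="0" POSITION_Z="0"/>
    <Spot ID="3" FRAME="-1" POSITION_X="0" POSITION_Y="0" POSITION_Z="0"/>
    <Spot ID="4" FRAME="-2" POSITION_X="0" POSITION_Y="0" POSITION_Z="0"/>
    <Spot ID="5" FRAME="-1" POSITION_X="0" POSITION_Y="0" POSITION_Z="0"/>
    <Spot ID="6" FRAME="-1" POSITION_X="0" POSITION_Y="0" POSITION_Z="0"/>
    <Spot ID="7" FRAME="-2" POSITION_X="0" POSITION_Y="0" POSITION_Z="0"/>
    <Spot ID="8" FRAME="-1" POSITION_X="0" POSITION_Y="0" POSITION_Z="0"/>
    <Spot ID="9" FRAME="-1" POSITION_X="0" POSITION_Y="0" POSITION_Z="0"/>
  </AllSpots>
  <AllTracks>
    <Track name="f0001">
      <Edge SPOT_SOURCE_ID="1" SPOT_TARGET_ID="2"/>
      <Edge SPOT_SOURCE_ID="1" SPOT_TARGET_ID="3"/>
    </Track>
    <Track name="f0002">
      <Edge SPOT_SOURCE_ID="4" SPOT_TARGET_ID="5"/>
      <Edge SPOT_SOURCE_ID="4" SPOT_TARGET_ID="6"/>
    </Track>
    <Track name="f0003">
      <Edge SPOT_SOURCE_ID="7" SPOT_TARGET_ID="8"/>
      <Edge SPOT_SOURCE_ID="7" SPOT_TARGET_ID="9"/>
    </Track>
  </AllTracks>
</TrackModel>
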